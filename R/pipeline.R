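#' All-against-all seeded alignment of coding sequences
#'
#' Nucleotide counterpart of [align_genomes()] for the CDS RBH channel:
#' gene pairs sharing at least one DNA k-mer are aligned locally with a
#' match/mismatch scoring scheme.
#'
#' @param ann_q,ann_s `genome_annotation`s
#' @param queries optional subset of query gene ids
#' @param k DNA seed length
#' @param min_score minimum raw alignment score
#' @param match,mismatch nucleotide scores
#' @param gap_opening,gap_extension affine gap penalties
#' @return a [hit_table()]
#' @export
align_genomes_cds <- function(ann_q, ann_s, queries = NULL, k = 12L,
                              min_score = 50, match = 2, mismatch = -3,
                              gap_opening = 5, gap_extension = 2) {
  if (is.null(queries)) queries <- ann_q$genes$gene_id
  hits <- .align_all(ann_q$cds, ann_s$cds, queries, k, min_score,
                     .dna_matrix(match, mismatch), gap_opening,
                     gap_extension)
  hit_table(hits, ann_q$species_tag, ann_s$species_tag)
}

# Ks function over a set of genome annotations, with a pair cache.
.ks_fn <- function(annotations) {
  proteins <- unlist(lapply(annotations, `[[`, "protein"))
  cdss <- unlist(lapply(annotations, `[[`, "cds"))
  names(proteins) <- unlist(lapply(annotations, function(a) names(a$protein)))
  names(cdss) <- unlist(lapply(annotations, function(a) names(a$cds)))
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  function(gene_x, gene_y) {
    key <- paste(sort(c(gene_x, gene_y)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    aln <- align_protein_pair(proteins[[gene_x]], proteins[[gene_y]])
    r <- kaks_pairwise(backtranslate(aln, cdss[[gene_x]], cdss[[gene_y]]))
    cache[[key]] <- r$Ks
    r$Ks
  }
}

# Retained synteny blocks between two annotations (or self).
.synteny_blocks <- function(hits, ann_x, ann_y, params, ks_fn,
                            quota_x = NULL, quota_y = NULL) {
  self <- identical(ann_x$species_tag, ann_y$species_tag)
  strong <- hits[hits$bitscore >= params$synteny_min_score, , drop = FALSE]
  pairs <- anchor_pairs_from_hits(strong, ann_x, ann_y, self = self,
                                  tandem_window = params$tandem_spacer_window)
  blocks <- chain_all_sequences(pairs, params$chain_max_gap,
                                params$chain_min_size)
  blocks <- merge_blocks(blocks, params$block_merge_spacers)
  blocks <- suppressWarnings(
    ks_filter_blocks(blocks, ks_fn, params$block_ks_min, params$block_ks_max))
  if (self) {
    q <- max(1L, ann_x$syntenic_depth - 1L)
    screen_depth(blocks, q, q, same_genome = TRUE)
  } else {
    screen_depth(blocks,
                 quota_x %||% ann_y$syntenic_depth,
                 quota_y %||% ann_x$syntenic_depth)
  }
}

#' Presence/absence matrix of reference family genes across species
#'
#' For every reference family gene and every species, scores the evidence
#' as `RBH+synteny`, `RBH only`, `synteny only` or `absent`, and flags a
#' gene as a conserved cluster member when it has a syntenic ortholog in
#' every non-reference species. With `transitive_rescue`, a missing synteny
#' call in one species is rescued when the gene's RBH partner there is also
#' the RBH partner of one of the gene's syntenic orthologs in a third
#' species.
#'
#' @param reference_family character vector of reference gene ids
#' @param rbh_by_genome named list (species -> data.frame `gene_a`,
#'   `gene_b`) of RBH pairs with the reference
#' @param syntelogs_by_genome named list of syntenic pairs (same shape)
#' @param transitive_rescue enable the third-genome rescue rule
#' @return data.frame with one row per reference gene, one column per
#'   species, plus a logical `conserved` column
#' @export
presence_absence_matrix <- function(reference_family, rbh_by_genome,
                                    syntelogs_by_genome,
                                    transitive_rescue = FALSE) {
  species <- union(names(rbh_by_genome), names(syntelogs_by_genome))
  cells <- matrix("absent", nrow = length(reference_family),
                  ncol = length(species),
                  dimnames = list(reference_family, species))
  syn_ok <- matrix(FALSE, length(reference_family), length(species),
                   dimnames = list(reference_family, species))
  for (sp in species) {
    rbh <- rbh_by_genome[[sp]]
    syn <- syntelogs_by_genome[[sp]]
    for (g in reference_family) {
      has_rbh <- !is.null(rbh) && g %in% rbh$gene_a
      has_syn <- !is.null(syn) && g %in% syn$gene_a
      syn_ok[g, sp] <- has_syn
      cells[g, sp] <- if (has_rbh && has_syn) "RBH+synteny"
                      else if (has_rbh) "RBH only"
                      else if (has_syn) "synteny only" else "absent"
    }
  }
  if (transitive_rescue) {
    for (g in reference_family) {
      missing_sp <- species[!syn_ok[g, ]]
      if (length(missing_sp) == 0L || all(!syn_ok[g, ])) next
      for (sp in missing_sp) {
        rbh <- rbh_by_genome[[sp]]
        if (is.null(rbh)) next
        partners <- rbh$gene_b[rbh$gene_a == g]
        if (length(partners) == 0L) next
        # syntenic orthologs of g elsewhere
        others <- unlist(lapply(species[syn_ok[g, ]], function(s2)
          syntelogs_by_genome[[s2]]$gene_b[
            syntelogs_by_genome[[s2]]$gene_a == g]), use.names = FALSE)
        # rescue if any partner is RBH-linked to one of those orthologs
        linked <- any(vapply(species[syn_ok[g, ]], function(s2) {
          r2 <- rbh_by_genome[[s2]]
          any(r2$gene_b[r2$gene_a == g] %in% others)
        }, logical(1))) && length(others) > 0
        if (linked) {
          syn_ok[g, sp] <- TRUE
          cells[g, sp] <- paste0(cells[g, sp], "+rescued")
        }
      }
    }
  }
  out <- data.frame(gene_id = reference_family, cells,
                    conserved = apply(syn_ok, 1L, all),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the full family-curation pipeline
#'
#' Executes, in order: (1) the three RBH channels plus reference synteny to
#' build the anchor pool; (2) the forward/reverse expansion screen; (3) the
#' domain consensus and NB-ARC-and-LRR filter; (4) tandem-array detection;
#' (5) self-synteny blocks and ohnolog groups; (6) duplicate
#' classification; (7) class pairing and Ka/Ks; (8) report assembly. Fully
#' deterministic for fixed inputs.
#'
#' @param annotations named list of `genome_annotation`s; the reference
#'   genome must be among them
#' @param reference species tag of the reference genome
#' @param reference_family non-empty vector of curated reference family
#'   gene ids (the seed set extended by the screen)
#' @param params a [pipeline_params()]
#' @param hit_source `"builtin"` (seeded aligner) or `"precomputed"`
#' @param hits for `"precomputed"`: list with elements `protein` and `cds`,
#'   each a named list of `hit_table`s keyed `"qtag|stag"` (protein tables
#'   for all ordered genome pairs including self; cds tables for reference
#'   vs each genome, both directions)
#' @param domain_source `"toy"` (motif annotator) or `"precomputed"`
#' @param domain_calls for `"precomputed"`: a domain-call data.frame
#' @param out_dir optional directory for per-stage TSV artifacts
#' @param verbose print per-stage counts
#' @return a family report: list with per-species `family` table, `venn`,
#'   `table1`, `table2`, `class_rates`, `class_summary`, `matrix`,
#'   `candidates`, `anchors`, `arrays`, `ohnolog_groups`, `labels`,
#'   `stage_counts`
#' @export
run_pipeline <- function(annotations, reference, reference_family,
                         params = pipeline_params(),
                         hit_source = c("builtin", "precomputed"),
                         hits = NULL,
                         domain_source = c("toy", "precomputed"),
                         domain_calls = NULL,
                         out_dir = NULL, verbose = TRUE) {
  hit_source <- match.arg(hit_source)
  domain_source <- match.arg(domain_source)
  stopifnot(reference %in% names(annotations))
  if (length(reference_family) == 0L)
    stop("reference_family must not be empty", call. = FALSE)
  tags <- names(annotations)
  say <- function(...) if (verbose) message(sprintf(...))
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.table(df, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  stage_counts <- list()

  # ---- stage 0: homology hits ---------------------------------------
  key <- function(q, s) paste(q, s, sep = "|")
  H <- list(); Hc <- list()
  if (hit_source == "builtin") {
    for (q in tags) for (s in tags)
      H[[key(q, s)]] <- align_genomes(annotations[[q]], annotations[[s]])
    for (s in setdiff(tags, reference)) {
      Hc[[key(reference, s)]] <-
        align_genomes_cds(annotations[[reference]], annotations[[s]])
      Hc[[key(s, reference)]] <-
        align_genomes_cds(annotations[[s]], annotations[[reference]])
    }
  } else {
    H <- hits$protein
    Hc <- hits$cds %||% list()
    need <- as.vector(outer(tags, tags, key))
    if (!all(need %in% names(H)))
      stop("precomputed protein hits missing for: ",
           paste(setdiff(need, names(H)), collapse = ", "), call. = FALSE)
  }
  say("stage 0: %d protein hit tables, %d cds hit tables",
      length(H), length(Hc))

  ks_fn <- .ks_fn(annotations)
  prot_len <- lapply(annotations, function(a) nchar(a$protein))
  cds_len <- lapply(annotations, function(a) nchar(a$cds))

  # ---- stage 1: RBH channels + reference synteny -> anchor pool ------
  anchors_by_genome <- list()
  rbh_by_genome <- list()
  syntelogs_by_genome <- list()
  for (s in setdiff(tags, reference)) {
    hab <- H[[key(reference, s)]]
    hba <- H[[key(s, reference)]]
    rbh_f <- reciprocal_best_hits(hab, hba, "protein_filtered",
                                  prot_len[[reference]], prot_len[[s]],
                                  params$length_ratio_min,
                                  params$length_ratio_max)
    rbh_p <- reciprocal_best_hits(hab, hba, "protein",
                                  prot_len[[reference]], prot_len[[s]])
    rbh_c <- if (!is.null(Hc[[key(reference, s)]]))
      reciprocal_best_hits(Hc[[key(reference, s)]], Hc[[key(s, reference)]],
                           "cds", cds_len[[reference]], cds_len[[s]])
      else rbh_p[0, ]
    blocks <- .synteny_blocks(hab, annotations[[reference]],
                              annotations[[s]], params, ks_fn)
    syn_pairs <- do.call(rbind, lapply(blocks, function(b)
      data.frame(gene_a = b$pairs$gene_x, gene_b = b$pairs$gene_y,
                 stringsAsFactors = FALSE)))
    if (is.null(syn_pairs))
      syn_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                              stringsAsFactors = FALSE)
    anchors_by_genome[[s]] <-
      build_anchor_pool(rbh_f, rbh_p, rbh_c, syn_pairs)
    rbh_by_genome[[s]] <- unique(rbind(rbh_f[c("gene_a", "gene_b")],
                                       rbh_p[c("gene_a", "gene_b")],
                                       rbh_c[c("gene_a", "gene_b")]))
    syntelogs_by_genome[[s]] <- unique(syn_pairs)
    emit(anchors_by_genome[[s]], paste0("anchors_", s))
  }
  anchors <- unique(c(unlist(lapply(anchors_by_genome, `[[`, "gene_id"),
                             use.names = FALSE),
                      reference_family))
  stage_counts$anchors <- length(anchors)
  say("stage 1: anchor pool of %d genes", length(anchors))

  # ---- stage 2: forward/reverse expansion ----------------------------
  forward_hits <- setNames(lapply(tags, function(s) {
    tabs_q <- lapply(tags, function(q) as.data.frame(H[[key(q, s)]]))
    hit_table(do.call(rbind, tabs_q), "anchors", s)
  }), tags)
  reverse_hits <- setNames(lapply(tags, function(s) H[[key(s, reference)]]),
                           tags)
  candidates <- expand_family(anchors, forward_hits, reverse_hits,
                              reference_family, params$reverse_max_targets)
  stage_counts$candidates <- vapply(candidates, length, integer(1))
  say("stage 2: candidates per genome: %s",
      paste(names(candidates), stage_counts$candidates, collapse = ", "))

  # ---- stage 3: domain consensus + family filter ---------------------
  if (domain_source == "toy") {
    calls <- do.call(rbind, lapply(tags, function(s) {
      ann <- annotations[[s]]
      do.call(rbind, lapply(candidates[[s]], function(g)
        toy_annotate(ann$protein[[g]], g)))
    }))
    if (is.null(calls)) calls <- toy_annotate("M", "none")[0, ]
  } else {
    if (is.null(domain_calls))
      stop("domain_source = 'precomputed' requires domain_calls",
           call. = FALSE)
    calls <- domain_calls
  }
  family_by_genome <- list()
  arch_by_genome <- list()
  venn_by_genome <- list()
  for (s in tags) {
    arch <- consensus_architecture(calls, genes = candidates[[s]],
                                   required_domains = params$required_domains,
                                   min_predictors = params$min_predictors)
    arch_by_genome[[s]] <- arch
    family_by_genome[[s]] <- arch$gene_id[arch$family_member]
    has <- function(d) unique(calls$gene_id[calls$domain_label == d &
                                              calls$gene_id %in% candidates[[s]]])
    venn_by_genome[[s]] <- venn_counts(has("NB-ARC"), has("LRR"), has("TIR"))
    emit(arch, paste0("architecture_", s))
  }
  stage_counts$family <- vapply(family_by_genome, length, integer(1))
  say("stage 3: family members per genome: %s",
      paste(tags, stage_counts$family, collapse = ", "))

  # ---- stages 4-6: tandem arrays, self-synteny, classification -------
  arrays_by_genome <- list()
  groups_by_genome <- list()
  labels_by_genome <- list()
  ohno_genomewide <- list()
  for (s in tags) {
    ann <- annotations[[s]]
    self_hits <- H[[key(s, s)]]
    arrays_by_genome[[s]] <- detect_tandem_arrays(
      family_by_genome[[s]], ann, self_hits, params$tandem_spacer_window)
    blocks <- .synteny_blocks(self_hits, ann, ann, params, ks_fn)
    groups_by_genome[[s]] <- assign_ohnolog_groups(blocks,
                                                   family_by_genome[[s]])
    ohno_genomewide[[s]] <- genes_in_blocks(blocks)
    labels_by_genome[[s]] <- classify_duplicates(
      family_by_genome[[s]], arrays_by_genome[[s]], groups_by_genome[[s]])
    emit(labels_by_genome[[s]], paste0("classes_", s))
    emit(arrays_to_table(arrays_by_genome[[s]], ann), paste0("arrays_", s))
  }
  say("stages 4-6: arrays per genome: %s",
      paste(tags, vapply(arrays_by_genome, length, integer(1)),
            collapse = ", "))

  # ---- stage 7: class pairing + Ka/Ks --------------------------------
  rate_rows <- list()
  for (s in tags) {
    pairs <- select_class_pairs(labels_by_genome[[s]], arrays_by_genome[[s]],
                                groups_by_genome[[s]], H[[key(s, s)]])
    if (nrow(pairs) == 0L) next
    ann <- annotations[[s]]
    for (i in seq_len(nrow(pairs))) {
      r <- rates_for_pair(ann, pairs$gene_a[i], pairs$gene_b[i])
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        species = s, gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
        class = pairs$class[i], S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
        Ka = r$Ka, Ks = r$Ks, omega = r$omega, stringsAsFactors = FALSE)
    }
  }
  class_rates <- if (length(rate_rows)) do.call(rbind, rate_rows) else
    data.frame(species = character(0), gene_a = character(0),
               gene_b = character(0), class = character(0), S = numeric(0),
               N = numeric(0), Sd = numeric(0), Nd = numeric(0),
               Ka = numeric(0), Ks = numeric(0), omega = numeric(0),
               stringsAsFactors = FALSE)
  class_summary <- if (nrow(class_rates))
    summarize_class_rates(class_rates) else NULL
  emit(class_rates, "class_rates")

  # ---- stage 8: report tables ----------------------------------------
  table1 <- summarize_arrays(arrays_by_genome,
                             vapply(family_by_genome, length, numeric(1)))
  table2 <- summarize_ohnologs(setNames(lapply(tags, function(s) {
    fam <- family_by_genome[[s]]
    list(n_ohno_genome = length(ohno_genomewide[[s]]),
         n_genes = nrow(annotations[[s]]$genes),
         n_ohno_family = length(intersect(fam, groups_by_genome[[s]]$gene_id)),
         n_family = max(1L, length(fam)))
  }), tags))
  pam <- presence_absence_matrix(reference_family, rbh_by_genome,
                                 syntelogs_by_genome)
  family_table <- do.call(rbind, lapply(tags, function(s) {
    arch <- arch_by_genome[[s]]
    fam <- arch[arch$family_member, c("gene_id", "subclass")]
    if (nrow(fam) == 0L) return(NULL)
    cbind(data.frame(species = s, stringsAsFactors = FALSE), fam)
  }))
  emit(table1, "table1_arrays")
  emit(table2, "table2_ohnologs")
  emit(pam, "presence_absence")
  if (!is.null(family_table)) emit(family_table, "family")

  list(family = family_table, venn = venn_by_genome, table1 = table1,
       table2 = table2, class_rates = class_rates,
       class_summary = class_summary, matrix = pam,
       candidates = candidates, anchors = anchors,
       arrays = arrays_by_genome, ohnolog_groups = groups_by_genome,
       labels = labels_by_genome, stage_counts = stage_counts)
}
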