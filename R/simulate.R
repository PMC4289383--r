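## Synthetic clades: small sets of genomes carrying a planted multi-domain
## gene family (tandem arrays, WGD-derived ohnolog copies at controlled Ks,
## singleton relatives) over a shared background gene complement, plus a
## ground-truth table, so every pipeline stage is testable offline.

# Integer-coded codon mutation tables: for each of the 64 codons, the 9
# single-base mutants, their class (1 synonymous, 2 nonsynonymous, 3 stop)
# and NG86 synonymous site counts.
.codon_tables <- local({
  tabs <- NULL
  function() {
    if (!is.null(tabs)) return(tabs)
    gc <- .genetic_code()
    codons <- names(gc)
    to <- matrix(0L, 64, 9, dimnames = list(codons, NULL))
    cls <- matrix(0L, 64, 9, dimnames = list(codons, NULL))
    for (ci in seq_along(codons)) {
      muts <- .codon_mutants(codons[ci])
      to[ci, ] <- match(muts, codons)
      cls[ci, ] <- ifelse(gc[muts] == "*", 3L,
                          ifelse(gc[muts] == gc[[codons[ci]]], 1L, 2L))
    }
    s_sites <- vapply(codons, function(cd) {
      if (gc[[cd]] == "*") return(NA_real_)
      .ng86_cache()[[cd]]
    }, numeric(1))
    tabs <<- list(codons = codons, to = to, class = cls,
                  S = s_sites, aa = gc,
                  n_syn = rowSums(cls == 1L), n_non = rowSums(cls == 2L))
    tabs
  }
})

#' Evolve a coding sequence to target synonymous divergence and Ka/Ks
#'
#' Codon-wise substitution simulator calibrated against the NG86 estimator:
#' the numbers of synonymous and nonsynonymous differences to plant are
#' `round(S * p)` and `round(N * p')`, where `p` and `p'` invert the
#' Jukes-Cantor correction at `target_ks` and `target_ks * target_omega`.
#' Each difference is applied at a distinct (codon, position) site, drawn
#' uniformly among the currently available single-base changes of the
#' requested class, and placements are kept attribution-coherent: a change
#' is accepted only if NG86 pathway averaging over (original, mutated)
#' codon recovers exactly the planted event classes (with a documented
#' fallback when no coherent placement exists), so the corrected NG86
#' estimates are centred tightly on the targets. Stop codons are never
#' created and sequence length is preserved. Codons listed in `keep_aa`
#' accept synonymous changes only, so planted amino-acid motifs survive
#' divergence, as conserved domains do.
#'
#' A terminal stop codon, if present, is left untouched. Targets are
#' unreachable (an error) when the required number of changes exceeds the
#' sites available, e.g. a nonsynonymous target on a fully protected
#' sequence.
#'
#' @param cds coding sequence (sense codons; optional terminal stop)
#' @param target_ks expected synonymous substitutions per synonymous site;
#'   must be finite and below the NG86 saturation bound
#' @param target_omega expected Ka/Ks of the applied process (default 1)
#' @param seed integer seed; same inputs give identical output
#' @param keep_aa integer codon positions whose amino acid must not change
#' @return the diverged coding sequence
#' @export
evolve_cds <- function(cds, target_ks, target_omega = 1, seed = 1,
                       keep_aa = integer(0)) {
  if (target_ks < 0 || target_omega < 0)
    stop("targets must be non-negative", call. = FALSE)
  cds <- toupper(cds)
  stop_tail <- ""
  stripped <- strip_terminal_stop(cds)
  if (nchar(stripped) < nchar(cds))
    stop_tail <- substr(cds, nchar(cds) - 2L, nchar(cds))
  tabs <- .codon_tables()
  idx <- match(split_codons(stripped), tabs$codons)
  if (anyNA(idx) || any(tabs$aa[idx] == "*"))
    stop("CDS contains an unrecognized or internal stop codon", call. = FALSE)
  L <- length(idx)
  if (target_ks == 0 || L == 0L)
    return(cds)
  S_all <- sum(tabs$S[idx])
  N_all <- 3 * L - S_all
  keep_aa <- keep_aa[keep_aa >= 1L & keep_aa <= L]
  protected <- rep(FALSE, L)
  protected[keep_aa] <- TRUE
  # invert the JC correction: proportions of sites that must end up changed
  jc_inv <- function(k) 0.75 * (1 - exp(-4 * k / 3))
  p_syn <- jc_inv(target_ks)
  p_non <- jc_inv(target_ks * target_omega)
  pos_of_slot <- rep(1:3, each = 3L)
  orig_idx <- idx
  with_seed(seed, {
    n_syn <- round(p_syn * S_all)
    n_non <- round(p_non * N_all)
    events <- sample(c(rep(1L, n_syn), rep(2L, n_non)))
    used <- matrix(FALSE, L, 3L)     # one change per (codon, position)
    s_cnt <- integer(L); n_cnt <- integer(L)  # planted events per codon
    count_avail <- function(row, ev) {
      cl <- tabs$class[idx[row], ]
      sum(cl == ev & !used[row, pos_of_slot])
    }
    # a proposed change is attribution-coherent when NG86 pathway averaging
    # over (original codon, new codon) recovers exactly the planted event
    # classes at that codon, so the estimator sees what was planted
    pc <- .pairwise_counts()
    coherent <- function(row, slot, ev) {
      new_idx <- tabs$to[idx[row], slot]
      sd <- pc$SD[orig_idx[row], new_idx]
      if (is.na(sd)) return(FALSE)
      abs(sd - (s_cnt[row] + (ev == 1L))) < 1e-9 &&
        abs(pc$ND[orig_idx[row], new_idx] - (n_cnt[row] + (ev == 2L))) < 1e-9
    }
    w_s <- tabs$n_syn[idx]
    w_n <- ifelse(protected, 0L, tabs$n_non[idx])
    for (ev in events) {
      w_base <- if (ev == 1L) w_s else w_n
      w <- w_base
      placed <- FALSE
      fallback <- NULL                # first available but incoherent pick
      while (!placed) {
        cw <- cumsum(w)
        tot <- cw[L]
        if (tot == 0L) break
        row <- findInterval(runif(1L) * tot, cw) + 1L
        cl <- tabs$class[idx[row], ]
        slots <- which(cl == ev & !used[row, pos_of_slot])
        slots <- slots[sample.int(length(slots))]
        ok <- slots[vapply(slots, function(sl) coherent(row, sl, ev),
                           logical(1))]
        if (length(ok)) {
          slot <- ok[[1L]]
          placed <- TRUE
        } else {
          if (is.null(fallback))
            fallback <- list(row = row, slot = slots[[1L]])
          w[row] <- 0L                # try another codon for this event
          next
        }
        used[row, pos_of_slot[slot]] <- TRUE
        idx[row] <- tabs$to[idx[row], slot]
        s_cnt[row] <- s_cnt[row] + (ev == 1L)
        n_cnt[row] <- n_cnt[row] + (ev == 2L)
        w_s[row] <- count_avail(row, 1L)
        w_n[row] <- if (protected[row]) 0L else count_avail(row, 2L)
      }
      if (!placed) {
        if (is.null(fallback))
          stop("unreachable target: no available ",
               c("synonymous", "nonsynonymous")[ev], " change", call. = FALSE)
        row <- fallback$row; slot <- fallback$slot
        used[row, pos_of_slot[slot]] <- TRUE
        idx[row] <- tabs$to[idx[row], slot]
        s_cnt[row] <- s_cnt[row] + (ev == 1L)
        n_cnt[row] <- n_cnt[row] + (ev == 2L)
        w_s[row] <- count_avail(row, 1L)
        w_n[row] <- if (protected[row]) 0L else count_avail(row, 2L)
      }
    }
  })
  paste0(paste(tabs$codons[idx], collapse = ""), stop_tail)
}

# Random sense-codon CDS of n_codons (ATG start, no stops), as a string.
.random_cds <- function(n_codons) {
  tabs <- .codon_tables()
  sense <- which(tabs$aa != "*" & tabs$codons != "ATG")
  picks <- sense[sample.int(length(sense), n_codons - 1L, replace = TRUE)]
  paste(c("ATG", tabs$codons[picks]), collapse = "")
}

# Codons encoding an amino-acid string (random synonymous choice).
.encode_protein <- function(aa_string) {
  gc <- .genetic_code()
  vapply(strsplit(aa_string, "")[[1]], function(a) {
    opts <- names(gc)[gc == a]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
}

# Overwrite codons `at` (1-based codon positions) of a CDS with codons
# encoding `aa_string`.
.plant_motif <- function(cds, aa_string, at) {
  codons <- split_codons(cds)
  codons[at:(at + nchar(aa_string) - 1L)] <- .encode_protein(aa_string)
  paste(codons, collapse = "")
}

#' Configuration of a synthetic clade
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: three genomes descending from one ancestor (star topology, one
#' divergence step per species branch), two chromosomes, a planted family
#' of nine ancestral loci per genome expanded into three tandem arrays
#' (sizes 4, 3, 2 at the given spacer counts), three whole-genome-
#' duplication ohnolog loci (chromosome 2 duplicated at the target Ks), and
#' three singleton paralog pairs placed far apart on chromosome 1. Class
#' divergence targets: tandem pairs Ks 0.2 at omega 1.6, ohnolog pairs Ks
#' 0.3 (the WGD age) at omega 1.35, singleton pairs Ks 0.25 at omega 1.2 --
#' recent, lineage-specific duplications whose proteins remain reliably
#' alignable (about 45-55 percent identity at these strongly positive
#' omega values).
#'
#' @param seed master seed; all randomness derives from it
#' @param n_genomes number of genomes (first is the reference)
#' @param species_tags species identifiers
#' @param array_spec list of tandem arrays, each `list(size =, spacers =)`
#'   with `size - 1` spacer counts (intervening background genes between
#'   consecutive members)
#' @param n_ohnolog_loci family loci on the duplicated chromosome
#' @param n_singleton_pairs singleton paralog pairs on chromosome 1
#' @param wgd list `present`, `target_ks` (divergence of the duplicated
#'   chromosome copy)
#' @param class_omega named targets for `tandem`, `ohnolog`, `singleton`
#' @param class_ks named Ks targets for `tandem` and `singleton` pairs
#' @param background list `ks`, `omega`: per-species-branch divergence of
#'   every gene from the ancestor
#' @param locus_ks,locus_omega divergence between distinct ancestral family
#'   loci; the default is deep (effectively saturated Ks, as between real
#'   multi-gene-family lineages), so within-class partners are clearly each
#'   other's best hits while cross-locus homology survives only in the
#'   conserved motifs
#' @param family_codons,background_codons protein lengths in codons
#' @param chr1_separator background genes between family placements on
#'   chromosome 1 (kept above both the tandem window and the chaining gap)
#' @param chr1_flank,chr2_separator,chr2_flank background run lengths
#' @param tir_fraction fraction of family loci carrying a TIR domain
#' @return object of class `clade_config`
#' @export
clade_config <- function(seed = 101L,
                         n_genomes = 3L,
                         species_tags = paste0("sp", seq_len(n_genomes)),
                         array_spec = list(list(size = 4L, spacers = c(1L, 2L, 0L)),
                                           list(size = 3L, spacers = c(2L, 5L)),
                                           list(size = 2L, spacers = 0L)),
                         n_ohnolog_loci = 3L,
                         n_singleton_pairs = 3L,
                         wgd = list(present = TRUE, target_ks = 0.3),
                         class_omega = c(tandem = 1.6, ohnolog = 1.35,
                                         singleton = 1.2),
                         class_ks = c(tandem = 0.2, singleton = 0.25),
                         background = list(ks = 0.15, omega = 0.5),
                         locus_ks = 3.0, locus_omega = 0.8,
                         family_codons = 300L, background_codons = 80L,
                         chr1_separator = 22L, chr1_flank = 12L,
                         chr2_separator = 12L, chr2_flank = 6L,
                         tir_fraction = 0.5) {
  stopifnot(n_genomes >= 1L, length(species_tags) == n_genomes,
            wgd$target_ks >= 0, all(class_omega > 0), all(class_ks >= 0))
  for (a in array_spec) {
    stopifnot(a$size >= 2L, length(a$spacers) == a$size - 1L,
              all(a$spacers >= 0L))
  }
  structure(as.list(environment()), class = "clade_config")
}

# Layout of one ancestral chromosome: data.frame of slots with role and
# locus labels, in gene order.
.slot <- function(role, locus, array = NA_character_) {
  data.frame(role = role, locus = locus, array = array,
             stringsAsFactors = FALSE)
}

.build_layout <- function(cfg) {
  bg_i <- 0L
  bg_run <- function(n) {
    if (n == 0L) return(NULL)
    ids <- sprintf("B%03d", bg_i + seq_len(n))
    bg_i <<- bg_i + n
    do.call(rbind, lapply(ids, function(b) .slot("bg", b)))
  }
  chr1 <- bg_run(cfg$chr1_flank)
  locus_i <- 0L
  groups <- list()
  for (ai in seq_along(cfg$array_spec)) {
    a <- cfg$array_spec[[ai]]
    locus_i <- locus_i + 1L
    lab <- sprintf("L%02d", locus_i)
    rows <- .slot("array_member", lab, sprintf("arr%d", ai))
    for (mi in seq_len(a$size - 1L)) {
      rows <- rbind(rows, bg_run(a$spacers[mi]),
                    .slot("array_member", lab, sprintf("arr%d", ai)))
    }
    groups[[length(groups) + 1L]] <- rows
  }
  for (si in seq_len(cfg$n_singleton_pairs)) {
    locus_i <- locus_i + 1L
    lab <- sprintf("L%02d", locus_i)
    groups[[length(groups) + 1L]] <- .slot("singleton", lab)
    groups[[length(groups) + 1L]] <- .slot("singleton_copy", lab)
  }
  for (g in groups) chr1 <- rbind(chr1, g, bg_run(cfg$chr1_separator))
  chr1 <- rbind(chr1, bg_run(cfg$chr1_flank))
  chr2 <- bg_run(cfg$chr2_flank)
  for (oi in seq_len(cfg$n_ohnolog_loci)) {
    locus_i <- locus_i + 1L
    lab <- sprintf("L%02d", locus_i)
    chr2 <- rbind(chr2, .slot("ohnolog", lab), bg_run(cfg$chr2_separator))
  }
  chr2 <- rbind(chr2, bg_run(cfg$chr2_flank))
  list(chr1 = chr1, chr2 = chr2, n_loci = locus_i)
}

#' Generate a synthetic clade with planted family structure
#'
#' Deterministic given the config seed. Family proteins carry the planted
#' NB-ARC signature, three LRR repeat motifs and (for a configurable
#' fraction of loci) a TIR signature; motif codons are protected against
#' amino-acid change during divergence, as conserved domains are. Each
#' species' genes diverge from the ancestor along a star topology; tandem
#' copies, singleton partners and the duplicated chromosome (WGD) are then
#' created within each species at the configured class Ks and omega
#' targets. Background genes are unrelated random coding sequences shared
#' (and diverged) across the clade, so collinear blocks are detectable.
#'
#' @param cfg a [clade_config()]
#' @return list with `annotations` (named list of `genome_annotation`),
#'   `domain_calls` (toy-annotator calls for every gene), `truth`
#'   (data.frame: species, gene_id, seq_id, family, class, array_id, locus,
#'   ohnolog_partner, domains), and `config`
#' @export
generate_clade <- function(cfg = clade_config()) {
  stopifnot(inherits(cfg, "clade_config"))
  motifs <- famscape_motifs()
  layout <- .build_layout(cfg)
  seeds <- derive_seeds(cfg$seed, 6L + cfg$n_genomes)

  # ---- ancestral sequences -------------------------------------------
  ancestral <- with_seed(seeds[1L], {
    fam_codons <- cfg$family_codons
    proto <- .random_cds(fam_codons)
    proto <- .plant_motif(proto, motifs$nbarc, 40L)
    lrr_at <- c(200L, 215L, 230L)
    for (p in lrr_at) proto <- .plant_motif(proto, motifs$lrr, p)
    protect <- c(1L, 40L:(39L + nchar(motifs$nbarc)),
                 unlist(lapply(lrr_at, function(p)
                   p:(p + nchar(motifs$lrr) - 1L))))
    tir_at <- 10L
    tir_protect <- tir_at:(tir_at + nchar(motifs$tir) - 1L)
    n_loci <- layout$n_loci
    tir_loci <- seq_len(n_loci) <= round(cfg$tir_fraction * n_loci)
    locus_seeds <- derive_seeds(seeds[1L], n_loci)
    loci <- vector("list", n_loci)
    for (i in seq_len(n_loci)) {
      cds <- evolve_cds(proto, cfg$locus_ks, cfg$locus_omega,
                        seed = locus_seeds[i], keep_aa = protect)
      if (tir_loci[i]) cds <- .plant_motif(cds, motifs$tir, tir_at)
      loci[[i]] <- list(
        cds = cds,
        protect = if (tir_loci[i]) c(protect, tir_protect) else protect,
        tir = tir_loci[i])
    }
    bg_ids <- unique(c(layout$chr1$locus[layout$chr1$role == "bg"],
                       layout$chr2$locus[layout$chr2$role == "bg"]))
    bgs <- setNames(lapply(bg_ids, function(b)
      .random_cds(cfg$background_codons)), bg_ids)
    list(loci = loci, bgs = bgs)
  })

  # ---- per-species genomes -------------------------------------------
  annotations <- list()
  truth_rows <- list()
  call_rows <- list()
  for (gi in seq_len(cfg$n_genomes)) {
    tag <- cfg$species_tags[gi]
    gseed <- seeds[6L + gi]
    sub <- derive_seeds(gseed, 4000L)
    si <- 0L
    next_seed <- function() { si <<- si + 1L; sub[si] }

    # species copies of every ancestral sequence
    sp_locus <- lapply(seq_along(ancestral$loci), function(i) {
      l <- ancestral$loci[[i]]
      evolve_cds(l$cds, cfg$background$ks, cfg$background$omega,
                 seed = sub[i], keep_aa = l$protect)
    })
    si <- length(ancestral$loci)
    sp_bg <- lapply(ancestral$bgs, function(cds)
      evolve_cds(cds, cfg$background$ks, cfg$background$omega,
                 seed = next_seed()))
    names(sp_bg) <- names(ancestral$bgs)

    locus_protect <- lapply(ancestral$loci, `[[`, "protect")
    locus_labels <- sprintf("L%02d", seq_along(ancestral$loci))

    genes <- list()   # per gene: id fields filled later
    add_gene <- function(chr, cds, role, locus, array = NA_character_,
                         partner_of = NA_character_) {
      genes[[length(genes) + 1L]] <<- list(
        chr = chr, cds = cds, role = role, locus = locus, array = array,
        partner_of = partner_of)
      length(genes)
    }

    emit_chr <- function(chr_name, slots) {
      arr_member_count <- list()
      for (k in seq_len(nrow(slots))) {
        s <- slots[k, ]
        if (s$role == "bg") {
          add_gene(chr_name, sp_bg[[s$locus]], "bg", s$locus)
        } else if (s$role == "array_member") {
          li <- match(s$locus, locus_labels)
          cnt <- (arr_member_count[[s$locus]] %||% 0L) + 1L
          arr_member_count[[s$locus]] <- cnt
          cds <- if (cnt == 1L) sp_locus[[li]] else
            evolve_cds(sp_locus[[li]], cfg$class_ks[["tandem"]],
                       cfg$class_omega[["tandem"]], seed = next_seed(),
                       keep_aa = locus_protect[[li]])
          add_gene(chr_name, cds, "tandem", s$locus, s$array)
        } else if (s$role == "singleton") {
          li <- match(s$locus, locus_labels)
          add_gene(chr_name, sp_locus[[li]], "singleton", s$locus)
        } else if (s$role == "singleton_copy") {
          li <- match(s$locus, locus_labels)
          cds <- evolve_cds(sp_locus[[li]], cfg$class_ks[["singleton"]],
                            cfg$class_omega[["singleton"]],
                            seed = next_seed(),
                            keep_aa = locus_protect[[li]])
          add_gene(chr_name, cds, "singleton", s$locus)
        } else if (s$role == "ohnolog") {
          li <- match(s$locus, locus_labels)
          add_gene(chr_name, sp_locus[[li]], "ohnolog", s$locus)
        }
      }
    }
    emit_chr("chr1", layout$chr1)
    chr2_start <- length(genes) + 1L
    emit_chr("chr2", layout$chr2)
    chr2_idx <- chr2_start:length(genes)

    if (isTRUE(cfg$wgd$present)) {
      for (k in chr2_idx) {
        g <- genes[[k]]
        li <- match(g$locus, locus_labels)
        fam <- g$role == "ohnolog"
        cds <- evolve_cds(
          g$cds, cfg$wgd$target_ks,
          if (fam) cfg$class_omega[["ohnolog"]] else cfg$background$omega,
          seed = next_seed(),
          keep_aa = if (fam) locus_protect[[li]] else integer(0))
        add_gene("chr2b", cds, if (fam) "ohnolog" else "bg", g$locus,
                 partner_of = as.character(k))
      }
    }

    # materialize gene models: ids in coordinate order per chromosome
    strands <- with_seed(next_seed(),
                         sample(c("+", "-"), length(genes), replace = TRUE))
    chrs <- vapply(genes, `[[`, character(1), "chr")
    pos_in_chr <- stats::ave(seq_along(chrs), chrs, FUN = seq_along)
    id_by_index <- sprintf("%s_g%04d", tag, seq_along(genes))
    starts <- (pos_in_chr - 1L) * 2000L + 101L
    cds_full <- paste0(vapply(genes, `[[`, character(1), "cds"), "TAA")
    gene_df <- data.frame(
      gene_id = id_by_index, seq_id = chrs, start = starts,
      end = starts + nchar(cds_full) - 1L, strand = strands,
      stringsAsFactors = FALSE)
    cds_v <- setNames(cds_full, id_by_index)
    prot_v <- setNames(vapply(genes, function(g) translate_cds(g$cds),
                              character(1)), id_by_index)
    ann <- genome_annotation(tag, gene_df, cds_v, prot_v,
                             syntenic_depth = if (isTRUE(cfg$wgd$present)) 2L else 1L)
    annotations[[tag]] <- ann

    roles <- vapply(genes, `[[`, character(1), "role")
    fam <- roles %in% c("tandem", "ohnolog", "singleton")
    partner_of <- vapply(genes, `[[`, character(1), "partner_of")
    arrays <- vapply(genes, `[[`, character(1), "array")
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      species = tag, gene_id = id_by_index,
      seq_id = vapply(genes, `[[`, character(1), "chr"),
      family = fam,
      class = ifelse(fam, roles, NA_character_),
      array_id = ifelse(is.na(arrays), NA_character_,
                        paste0(tag, "_", arrays)),
      locus = ifelse(fam, vapply(genes, `[[`, character(1), "locus"),
                     NA_character_),
      ohnolog_partner = ifelse(fam & !is.na(partner_of),
                               id_by_index[
                                 suppressWarnings(as.integer(partner_of))],
                               NA_character_),
      stringsAsFactors = FALSE)
    for (k in which(fam)) {
      calls <- toy_annotate(prot_v[[id_by_index[k]]], id_by_index[k])
      if (nrow(calls)) call_rows[[length(call_rows) + 1L]] <- calls
    }
  }
  truth <- do.call(rbind, truth_rows)
  # symmetrize ohnolog partner column
  has_p <- !is.na(truth$ohnolog_partner)
  back <- match(truth$ohnolog_partner[has_p], truth$gene_id)
  truth$ohnolog_partner[back] <- truth$gene_id[has_p]
  truth$domains <- NA_character_
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    toy_annotate("M", "none")[0, ]
  if (nrow(calls)) {
    dom_by_gene <- tapply(calls$domain_label, calls$gene_id,
                          function(d) paste(sort(unique(d)), collapse = ","))
    truth$domains <- unname(dom_by_gene[truth$gene_id])
  }
  rownames(truth) <- NULL
  list(annotations = annotations, domain_calls = calls, truth = truth,
       config = cfg)
}

#' Write a synthetic clade to disk in pipeline input formats
#'
#' Emits, per species, `<tag>.gff3`, `<tag>.cds.fa`, `<tag>.protein.fa`,
#' plus clade-wide `domains.tsv` (toy predictor dialect) and `truth.tsv`.
#'
#' @param sim result of [generate_clade()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_clade <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tag in names(sim$annotations)) {
    ann <- sim$annotations[[tag]]
    write_genome(ann,
                 file.path(dir, paste0(tag, ".gff3")),
                 file.path(dir, paste0(tag, ".cds.fa")),
                 file.path(dir, paste0(tag, ".protein.fa")))
  }
  write.table(sim$domain_calls, file.path(dir, "domains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
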