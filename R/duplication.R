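#' Detect tandem arrays of family genes
#'
#' A pair of family genes qualifies as a tandem pair iff both lie on the
#' same chromosome/scaffold, are separated by at most `window` intervening
#' gene models, and are linked by a homology hit in either direction
#' (self-hits removed; any stored hit counts, optionally subject to a
#' minimum percent identity). Hits between different sequences are ignored
#' (distant-location filter against transpositional duplicates). Arrays are
#' the connected components of qualifying pairs, with members ordered by
#' start coordinate.
#'
#' @param family_genes character vector of family gene ids
#' @param ann the `genome_annotation`
#' @param hits within-genome `hit_table` for this genome
#' @param window maximum allowed gene spacers (default 10)
#' @param min_identity optional minimum percent identity for a qualifying
#'   hit (default `NULL`: any hit links the pair)
#' @return list of arrays; each array is a list with `species_tag`,
#'   `seq_id`, `members` (gene ids ordered by start coordinate)
#' @export
detect_tandem_arrays <- function(family_genes, ann, hits, window = 10L,
                                 min_identity = NULL) {
  family_genes <- intersect(family_genes, ann$genes$gene_id)
  if (length(family_genes) < 2L) return(list())
  h <- as.data.frame(hits)
  h <- h[h$query_id != h$subject_id &
           h$query_id %in% family_genes &
           h$subject_id %in% family_genes, , drop = FALSE]
  if (!is.null(min_identity))
    h <- h[h$pct_identity >= min_identity, , drop = FALSE]
  if (nrow(h) == 0L) return(list())
  # undirected homology links
  a <- pmin(h$query_id, h$subject_id)
  b <- pmax(h$query_id, h$subject_id)
  links <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  g <- ann$genes
  ia <- match(links$a, g$gene_id)
  ib <- match(links$b, g$gene_id)
  same_seq <- g$seq_id[ia] == g$seq_id[ib]
  spacers <- abs(g$rank[ia] - g$rank[ib]) - 1L
  links <- links[same_seq & spacers <= window, , drop = FALSE]
  if (nrow(links) == 0L) return(list())
  gr <- igraph::graph_from_data_frame(links, directed = FALSE)
  comp <- igraph::components(gr)
  arrays <- list()
  for (cid in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == cid]
    ix <- match(members, g$gene_id)
    members <- members[order(g$start[ix])]
    arrays[[length(arrays) + 1L]] <- list(
      species_tag = ann$species_tag,
      seq_id = g$seq_id[match(members[1L], g$gene_id)],
      members = members)
  }
  # stable ordering: by seq then start of first member
  first_start <- vapply(arrays, function(a)
    g$start[match(a$members[1L], g$gene_id)], numeric(1))
  seqs <- vapply(arrays, `[[`, character(1), "seq_id")
  arrays[order(seqs, first_start)]
}

#' Classify family genes as tandem, ohnolog, tandem+ohnolog or singleton
#'
#' Membership flags are set from the tandem arrays and ohnolog groups. A
#' singleton is a family gene that is neither a tandem-array member nor in
#' a retained ohnolog group; genes in both pools are labelled
#' `tandem+ohnolog` and count once in each pool for downstream statistics
#' (the pools are not exclusive; only `singleton` is defined exclusively).
#'
#' @param family_genes character vector of family gene ids
#' @param arrays list of tandem arrays (see [detect_tandem_arrays()])
#' @param ohnolog_groups data.frame from [assign_ohnolog_groups()] (or NULL)
#' @return data.frame with columns `gene_id`, `is_tandem`, `is_ohnolog`,
#'   `klass`
#' @export
classify_duplicates <- function(family_genes, arrays, ohnolog_groups = NULL) {
  tandem <- unlist(lapply(arrays, `[[`, "members"), use.names = FALSE)
  ohno <- if (is.null(ohnolog_groups)) character(0) else ohnolog_groups$gene_id
  is_t <- family_genes %in% tandem
  is_o <- family_genes %in% ohno
  klass <- ifelse(is_t & is_o, "tandem+ohnolog",
           ifelse(is_t, "tandem",
           ifelse(is_o, "ohnolog", "singleton")))
  data.frame(gene_id = family_genes, is_tandem = is_t, is_ohnolog = is_o,
             klass = klass, stringsAsFactors = FALSE)
}

#' Tandem-array summary table (per species plus a totals row)
#'
#' Accepts either a named list of per-species array lists together with
#' family sizes, or a precomputed per-species counts table (columns
#' `species`, `family_size`, `n_tandem`, `n_arrays`, `largest_array`).
#' Reports, per species: family size, number of tandem duplicates (genes in
#' arrays), tandem fraction as a whole percent, array count, mean genes per
#' array (1 decimal) and the largest array; and a `Sigma` totals row with
#' summed counts, global fraction = total duplicates / total genes, mean
#' genes per array = total duplicates / total arrays, and the unweighted
#' mean of the per-species largest-array sizes. Percentages and means are
#' rounded half away from zero. An array-size histogram with the fraction
#' of two-gene arrays is attached as attribute `"size_histogram"`.
#'
#' @param arrays_by_species named list (species -> list of arrays), or a
#'   precomputed counts data.frame as described above
#' @param family_sizes named numeric vector of family sizes per species
#'   (ignored when a counts table is supplied)
#' @return data.frame; last row is the `Sigma` totals row
#' @export
summarize_arrays <- function(arrays_by_species, family_sizes = NULL) {
  if (is.data.frame(arrays_by_species)) {
    counts <- arrays_by_species
    sizes_all <- attr(arrays_by_species, "array_sizes") %||% integer(0)
  } else {
    counts <- do.call(rbind, lapply(names(arrays_by_species), function(sp) {
      arr <- arrays_by_species[[sp]]
      sz <- vapply(arr, function(a) length(a$members), integer(1))
      data.frame(species = sp,
                 family_size = as.numeric(family_sizes[[sp]]),
                 n_tandem = sum(sz), n_arrays = length(sz),
                 largest_array = if (length(sz)) max(sz) else 0L,
                 stringsAsFactors = FALSE)
    }))
    sizes_all <- unlist(lapply(arrays_by_species, function(arr)
      vapply(arr, function(a) length(a$members), integer(1))),
      use.names = FALSE)
  }
  pct <- function(num, den) if (den > 0) round_half_away(100 * num / den) else 0
  avg <- function(num, den) if (den > 0) round_half_away(num / den, 1) else 0
  per <- data.frame(
    species = counts$species,
    family_size = counts$family_size,
    n_tandem = counts$n_tandem,
    pct_tandem = mapply(pct, counts$n_tandem, counts$family_size),
    n_arrays = counts$n_arrays,
    mean_genes_per_array = mapply(avg, counts$n_tandem, counts$n_arrays),
    largest_array = counts$largest_array,
    stringsAsFactors = FALSE)
  sigma <- data.frame(
    species = "Sigma",
    family_size = sum(per$family_size),
    n_tandem = sum(per$n_tandem),
    pct_tandem = pct(sum(per$n_tandem), sum(per$family_size)),
    n_arrays = sum(per$n_arrays),
    mean_genes_per_array = avg(sum(per$n_tandem), sum(per$n_arrays)),
    largest_array = round_half_away(mean(per$largest_array), 1),
    stringsAsFactors = FALSE)
  out <- rbind(per, sigma)
  rownames(out) <- NULL
  if (length(sizes_all)) {
    hist <- as.data.frame(table(array_size = sizes_all),
                          stringsAsFactors = FALSE)
    names(hist) <- c("array_size", "n_arrays")
    hist$array_size <- as.integer(hist$array_size)
    attr(out, "size_histogram") <- hist
    attr(out, "frac_size2") <-
      sum(sizes_all == 2L) / length(sizes_all)
  }
  out
}

#' Ohnolog-retention summary table (per species plus a mean row)
#'
#' Per species: the percentage of genes in retained ohnolog groups
#' genome-wide and among family genes, plus an enrichment flag
#' (family percentage strictly greater than the genome-wide one). The
#' `Sigma` row holds the unweighted means of the per-species percentages,
#' rounded to one decimal.
#'
#' Accepts either raw inputs (named lists of ohnolog gene vectors plus
#' genome/family sizes) or a precomputed percentage table with columns
#' `species`, `pct_genomewide`, `pct_family`.
#'
#' @param x precomputed percentage data.frame, or a named list per species
#'   with elements `n_ohno_genome`, `n_genes`, `n_ohno_family`,
#'   `n_family`
#' @return data.frame; last row is the `Sigma` mean row
#' @export
summarize_ohnologs <- function(x) {
  if (is.data.frame(x)) {
    per <- x[c("species", "pct_genomewide", "pct_family")]
  } else {
    per <- do.call(rbind, lapply(names(x), function(sp) {
      v <- x[[sp]]
      data.frame(species = sp,
                 pct_genomewide = round_half_away(
                   100 * v$n_ohno_genome / v$n_genes),
                 pct_family = round_half_away(
                   100 * v$n_ohno_family / v$n_family),
                 stringsAsFactors = FALSE)
    }))
  }
  per$enriched <- per$pct_family > per$pct_genomewide
  sigma <- data.frame(
    species = "Sigma",
    pct_genomewide = round_half_away(mean(per$pct_genomewide), 1),
    pct_family = round_half_away(mean(per$pct_family), 1),
    enriched = NA, stringsAsFactors = FALSE)
  sigma$enriched <- sigma$pct_family > sigma$pct_genomewide
  out <- rbind(per, sigma)
  rownames(out) <- NULL
  out
}

#' Flatten tandem arrays to a membership table
#' @param arrays list of arrays
#' @param ann optional `genome_annotation` to add gene ranks
#' @return data.frame with columns `species`, `seq_id`, `array_id`,
#'   `gene_id`, `rank`
#' @export
arrays_to_table <- function(arrays, ann = NULL) {
  if (length(arrays) == 0L)
    return(data.frame(species = character(0), seq_id = character(0),
                      array_id = integer(0), gene_id = character(0),
                      rank = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_along(arrays), function(i) {
    a <- arrays[[i]]
    data.frame(species = a$species_tag, seq_id = a$seq_id, array_id = i,
               gene_id = a$members,
               rank = if (is.null(ann)) NA_integer_ else
                 ann$genes$rank[match(a$members, ann$genes$gene_id)],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
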