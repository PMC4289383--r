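#' Build rank-coordinate anchor pairs from a homology hit table
#'
#' Converts hits between two genomes (or a self-comparison) into the
#' gene-pair dot-plot points consumed by [chain_collinear_pairs()]. For a
#' self-comparison, self-hits are removed and pairs within the tandem
#' spacer window are excluded so tandem arrays cannot masquerade as
#' duplicated segments; mirror pairs are collapsed to one orientation.
#'
#' @param hits a `hit_table` with queries in `ann_x` and subjects in `ann_y`
#' @param ann_x,ann_y `genome_annotation`s (pass the same object twice for a
#'   self-comparison)
#' @param self `TRUE` for a self-comparison
#' @param tandem_window spacer window used to exclude near-diagonal
#'   self-pairs (only for `self = TRUE`)
#' @return data.frame with columns `gene_x`, `gene_y`, `seq_x`, `seq_y`,
#'   `rank_x`, `rank_y`
#' @export
anchor_pairs_from_hits <- function(hits, ann_x, ann_y, self = FALSE,
                                   tandem_window = 10L) {
  h <- as.data.frame(hits)[c("query_id", "subject_id")]
  h <- unique(h)
  gx <- ann_x$genes[match(h$query_id, ann_x$genes$gene_id), ]
  gy <- ann_y$genes[match(h$subject_id, ann_y$genes$gene_id), ]
  keep <- !is.na(gx$gene_id) & !is.na(gy$gene_id)
  pairs <- data.frame(gene_x = h$query_id, gene_y = h$subject_id,
                      seq_x = gx$seq_id, seq_y = gy$seq_id,
                      rank_x = gx$rank, rank_y = gy$rank,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (self) {
    pairs <- pairs[pairs$gene_x != pairs$gene_y, , drop = FALSE]
    near <- pairs$seq_x == pairs$seq_y &
      abs(pairs$rank_x - pairs$rank_y) - 1L <= tandem_window
    pairs <- pairs[!near, , drop = FALSE]
    # collapse mirror pairs to a canonical orientation
    flip <- pairs$seq_y < pairs$seq_x |
      (pairs$seq_x == pairs$seq_y & pairs$rank_y < pairs$rank_x)
    pairs[flip, c("gene_x", "gene_y", "seq_x", "seq_y", "rank_x", "rank_y")] <-
      pairs[flip, c("gene_y", "gene_x", "seq_y", "seq_x", "rank_y", "rank_x")]
    pairs <- unique(pairs)
  }
  rownames(pairs) <- NULL
  pairs
}

# Best collinear chain among pairs of one sequence pair, as row indices
# into `p`. Collinear scoring: chain score = number of chained pairs.
# Canonical choice among equal-score chains: smaller start rank_x, then
# smaller start rank_y, then orientation "same" before "inverted", then
# lexicographically smallest (rank_x, rank_y) sequence.
.best_chain <- function(p, max_gap) {
  n <- nrow(p)
  ord <- order(p$rank_x, p$rank_y)
  p <- p[ord, , drop = FALSE]
  best <- NULL
  for (orient in c(1, -1)) {
    f <- rep(1L, n)
    for (i in rev(seq_len(n))) {
      dx <- p$rank_x - p$rank_x[i]
      dy <- orient * (p$rank_y - p$rank_y[i])
      ok <- dx > 0 & dx <= max_gap & dy > 0 & dy <= max_gap
      if (any(ok)) f[i] <- 1L + max(f[ok])
    }
    len <- max(f)
    starts <- which(f == len)
    # smallest (rank_x, rank_y) start (rows are sorted, so first wins)
    i <- starts[1L]
    chain <- i
    while (f[i] > 1L) {
      dx <- p$rank_x - p$rank_x[i]
      dy <- orient * (p$rank_y - p$rank_y[i])
      nxt <- which(dx > 0 & dx <= max_gap & dy > 0 & dy <= max_gap &
                     f == f[i] - 1L)
      i <- nxt[1L]                      # sorted order = lexicographic
      chain <- c(chain, i)
    }
    cand <- list(rows = ord[chain], len = len,
                 start_x = p$rank_x[chain[1L]], start_y = p$rank_y[chain[1L]],
                 orientation = if (orient == 1) "same" else "inverted",
                 key = as.vector(rbind(p$rank_x[chain], p$rank_y[chain])))
    if (is.null(best) || .chain_better(cand, best)) best <- cand
  }
  best
}

.chain_better <- function(a, b) {
  if (a$len != b$len) return(a$len > b$len)
  if (a$start_x != b$start_x) return(a$start_x < b$start_x)
  if (a$start_y != b$start_y) return(a$start_y < b$start_y)
  if (a$orientation != b$orientation) return(a$orientation == "same")
  la <- length(a$key); lb <- length(b$key)
  k <- min(la, lb)
  d <- which(a$key[1:k] != b$key[1:k])
  if (length(d)) return(a$key[d[1L]] < b$key[d[1L]])
  la < lb
}

#' Chain collinear gene pairs into synteny blocks
#'
#' Dynamic programming over pairs of one sequence pair, in rank
#' coordinates. A pair extends a chain when both rank gaps are positive and
#' at most `max_gap`, with a consistent orientation (rank_y strictly
#' increasing for `same`, strictly decreasing for `inverted`). The chain
#' score is the number of chained pairs (collinear scoring). Blocks are
#' extracted best-score-first (ties by smaller start rank_x, then start
#' rank_y), each pair is assigned to at most one block, and chains below
#' `min_size` pairs are discarded.
#'
#' @param pairs data.frame with columns `gene_x`, `gene_y`, `rank_x`,
#'   `rank_y` (one seq_x/seq_y combination; optionally `seq_x`, `seq_y`)
#' @param max_gap maximum chaining distance in gene ranks (default 20)
#' @param min_size minimum pairs per block (default 5)
#' @return list of blocks; each block is a list with elements `pairs`
#'   (data.frame sorted by rank_x), `orientation`, `seq_x`, `seq_y`,
#'   `n_pairs`, `mean_ks` (NA until Ks is attached)
#' @export
chain_collinear_pairs <- function(pairs, max_gap = 20L, min_size = 5L) {
  pairs <- unique(pairs)
  blocks <- list()
  remaining <- pairs
  while (nrow(remaining) > 0L) {
    ch <- .best_chain(remaining, max_gap)
    if (ch$len < min_size) break
    bp <- remaining[ch$rows, , drop = FALSE]
    bp <- bp[order(bp$rank_x), , drop = FALSE]
    rownames(bp) <- NULL
    blocks[[length(blocks) + 1L]] <- list(
      pairs = bp,
      orientation = ch$orientation,
      seq_x = if (!is.null(bp$seq_x)) bp$seq_x[1L] else NA_character_,
      seq_y = if (!is.null(bp$seq_y)) bp$seq_y[1L] else NA_character_,
      n_pairs = nrow(bp),
      mean_ks = NA_real_)
    remaining <- remaining[-ch$rows, , drop = FALSE]
  }
  blocks
}

#' Chain collinear pairs across all sequence pairs
#'
#' Applies [chain_collinear_pairs()] within every (seq_x, seq_y)
#' combination of a genome-pair dot plot.
#'
#' @param pairs output of [anchor_pairs_from_hits()]
#' @inheritParams chain_collinear_pairs
#' @return flat list of blocks
#' @export
chain_all_sequences <- function(pairs, max_gap = 20L, min_size = 5L) {
  if (nrow(pairs) == 0L) return(list())
  key <- paste(pairs$seq_x, pairs$seq_y, sep = "\r")
  out <- list()
  for (k in sort(unique(key))) {
    sub <- pairs[key == k, , drop = FALSE]
    out <- c(out, chain_collinear_pairs(sub, max_gap, min_size))
  }
  out
}

.block_span <- function(block, axis = c("x", "y")) {
  axis <- match.arg(axis)
  r <- block$pairs[[paste0("rank_", axis)]]
  c(min(r), max(r))
}

# Number of gene ranks strictly between two rank intervals (0 when they
# touch or overlap) -- the "gene spacers" separating two blocks.
.interval_gap <- function(a, b) {
  max(0L, max(b[1L] - a[2L], a[1L] - b[2L]) - 1L)
}

#' Merge adjacent synteny blocks
#'
#' Two blocks on the same sequence pair and with the same orientation are
#' merged when the rank gap between their spans is at most
#' `block_merge_spacers` on both axes; merging is applied transitively.
#' The merged mean Ks is recomputed over all member pairs.
#'
#' @param blocks list of blocks (see [chain_collinear_pairs()])
#' @param block_merge_spacers maximum rank gap for merging (default 350)
#' @return list of merged blocks
#' @export
merge_blocks <- function(blocks, block_merge_spacers = 350L) {
  n <- length(blocks)
  if (n <= 1L) return(blocks)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bi <- blocks[[i]]; bj <- blocks[[j]]
      if (!identical(bi$seq_x, bj$seq_x) || !identical(bi$seq_y, bj$seq_y))
        next
      if (bi$orientation != bj$orientation) next
      gx <- .interval_gap(.block_span(bi, "x"), .block_span(bj, "x"))
      gy <- .interval_gap(.block_span(bi, "y"), .block_span(bj, "y"))
      if (gx <= block_merge_spacers && gy <= block_merge_spacers)
        adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comps <- igraph::components(g)$membership
  out <- list()
  for (cid in sort(unique(comps))) {
    members <- blocks[comps == cid]
    bp <- do.call(rbind, lapply(members, `[[`, "pairs"))
    bp <- bp[order(bp$rank_x, bp$rank_y), , drop = FALSE]
    rownames(bp) <- NULL
    ksv <- bp$ks
    out[[length(out) + 1L]] <- list(
      pairs = bp, orientation = members[[1L]]$orientation,
      seq_x = members[[1L]]$seq_x, seq_y = members[[1L]]$seq_y,
      n_pairs = nrow(bp),
      mean_ks = if (!is.null(ksv) && any(!is.na(ksv)))
        mean(ksv, na.rm = TRUE) else NA_real_)
  }
  out
}

#' Filter synteny blocks on mean Ks
#'
#' Attaches a pairwise Ks to every anchor pair via `rate_fn` (unless the
#' pairs already carry a `ks` column) and retains a block iff its mean Ks
#' lies within `[ks_min, ks_max]`. The default window \[0, 1.5\] removes
#' noise from recent lineage-specific duplications; windows for ancient WGD
#' events are fully configurable. Pairs where `rate_fn` fails are skipped
#' with a warning; a block with no computable pair is dropped with a
#' warning.
#'
#' @param blocks list of blocks
#' @param rate_fn function(gene_x, gene_y) returning a synonymous rate Ks
#'   (e.g. built on [rates_for_pair()]); ignored when pairs carry `ks`
#' @param ks_min,ks_max retained window for the block mean Ks
#' @return list of retained blocks, each with `mean_ks` filled in
#' @export
ks_filter_blocks <- function(blocks, rate_fn = NULL, ks_min = 0,
                             ks_max = 1.5) {
  out <- list()
  for (b in blocks) {
    if (is.null(b$pairs$ks)) {
      if (is.null(rate_fn))
        stop("blocks carry no ks and no rate_fn supplied", call. = FALSE)
      b$pairs$ks <- vapply(seq_len(nrow(b$pairs)), function(i) {
        val <- tryCatch(rate_fn(b$pairs$gene_x[i], b$pairs$gene_y[i]),
                        error = function(e) NA_real_)
        if (is.null(val) || length(val) != 1L) NA_real_ else as.numeric(val)
      }, numeric(1))
      if (anyNA(b$pairs$ks))
        warning(sum(is.na(b$pairs$ks)),
                " anchor pair(s) without computable Ks skipped")
    }
    ksv <- b$pairs$ks[!is.na(b$pairs$ks)]
    if (length(ksv) == 0L) {
      warning("block dropped: no computable Ks for any pair")
      next
    }
    b$mean_ks <- mean(ksv)
    if (b$mean_ks >= ks_min && b$mean_ks <= ks_max)
      out[[length(out) + 1L]] <- b
  }
  out
}

#' Greedy coverage-depth screen of synteny blocks
#'
#' Simplified stand-in for an integer-programming quota screen: blocks are
#' considered by pair count descending (ties by sequence and start rank); a
#' block is kept iff adding it would not raise the block multiplicity of
#' any gene rank it spans above `quota_x` on genome X or `quota_y` on
#' genome Y. For a self-comparison both spans of a block count against the
#' same genome's coverage.
#'
#' @param blocks list of blocks
#' @param quota_x,quota_y positive integer coverage quotas (e.g. 1:1 for
#'   unduplicated genome pairs)
#' @param same_genome `TRUE` when x and y are the same genome
#' @return list of retained blocks
#' @export
screen_depth <- function(blocks, quota_x = 1L, quota_y = 1L,
                         same_genome = FALSE) {
  if (length(blocks) == 0L) return(blocks)
  ord <- order(-vapply(blocks, `[[`, numeric(1), "n_pairs"),
               vapply(blocks, function(b) as.character(b$seq_x), character(1)),
               vapply(blocks, function(b) as.character(b$seq_y), character(1)),
               vapply(blocks, function(b) min(b$pairs$rank_x), numeric(1)),
               vapply(blocks, function(b) min(b$pairs$rank_y), numeric(1)))
  cov_x <- new.env(parent = emptyenv())
  cov_y <- if (same_genome) cov_x else new.env(parent = emptyenv())
  get_cov <- function(env, key) if (is.null(env[[key]])) 0L else env[[key]]
  keep <- logical(length(blocks))
  for (i in ord) {
    b <- blocks[[i]]
    sx <- .block_span(b, "x"); sy <- .block_span(b, "y")
    kx <- paste0(b$seq_x, ":", sx[1L]:sx[2L])
    ky <- paste0(b$seq_y, ":", sy[1L]:sy[2L])
    qx <- if (same_genome) max(quota_x, quota_y) else quota_x
    ok <- all(vapply(kx, get_cov, integer(1), env = cov_x) < qx) &&
      all(vapply(ky, get_cov, integer(1), env = cov_y) <
            (if (same_genome) qx else quota_y))
    if (ok) {
      keep[i] <- TRUE
      for (k in kx) cov_x[[k]] <- get_cov(cov_x, k) + 1L
      for (k in ky) cov_y[[k]] <- get_cov(cov_y, k) + 1L
    }
  }
  blocks[keep]
}

#' Genes participating in retained synteny blocks
#' @param blocks list of blocks
#' @return character vector of gene ids (union of both sides)
#' @export
genes_in_blocks <- function(blocks) {
  sort(unique(unlist(lapply(blocks, function(b)
    c(b$pairs$gene_x, b$pairs$gene_y)), use.names = FALSE)))
}

#' Group family genes into ohnolog groups from retained blocks
#'
#' For each family gene, its partners are the family genes it is anchored
#' to in retained blocks; groups are the connected components of these
#' partnerships. Groups are reported as pairs or triplets; larger
#' components are kept but flagged.
#'
#' @param blocks retained synteny blocks
#' @param family_genes character vector of family gene ids
#' @return data.frame with columns `group_id`, `gene_id`, `size`,
#'   `flagged` (`TRUE` for components larger than 3)
#' @export
assign_ohnolog_groups <- function(blocks, family_genes) {
  edges <- do.call(rbind, lapply(blocks, function(b)
    b$pairs[c("gene_x", "gene_y")]))
  empty <- data.frame(group_id = integer(0), gene_id = character(0),
                      size = integer(0), flagged = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) return(empty)
  edges <- edges[edges$gene_x %in% family_genes &
                   edges$gene_y %in% family_genes, , drop = FALSE]
  if (nrow(edges) == 0L) return(empty)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  out <- data.frame(group_id = as.integer(comp$membership),
                    gene_id = names(comp$membership),
                    stringsAsFactors = FALSE)
  out$size <- comp$csize[out$group_id]
  out$flagged <- out$size > 3L
  out <- out[order(out$group_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write synteny blocks as a tab-separated table
#' @param blocks list of blocks
#' @param file output path
#' @return the block summary data.frame, invisibly
#' @export
write_blocks <- function(blocks, file) {
  df <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block_id = i, seq_x = b$seq_x, seq_y = b$seq_y,
               orientation = b$orientation, n_pairs = b$n_pairs,
               mean_ks = b$mean_ks,
               pairs = paste(paste0(b$pairs$gene_x, "|", b$pairs$gene_y),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df))
    df <- data.frame(block_id = integer(0), seq_x = character(0),
                     seq_y = character(0), orientation = character(0),
                     n_pairs = integer(0), mean_ks = numeric(0),
                     pairs = character(0), stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
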