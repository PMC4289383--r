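.HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "evalue", "bitscore")

.empty_hits <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   pct_identity = numeric(0), aln_length = integer(0),
                   mismatches = integer(0), gap_opens = integer(0),
                   q_start = integer(0), q_end = integer(0),
                   s_start = integer(0), s_end = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Assemble a hit table
#'
#' A hit table is a data.frame of pairwise homology hits in the 12-column
#' tabular dialect (qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore), tagged with the query and subject
#' genome it belongs to. No e-value filtering is ever applied to it.
#'
#' @param hits data.frame with the 12 hit columns (see `parse_hit_table`)
#' @param query_genome,subject_genome species tags
#' @return object of class `hit_table` (a data.frame)
#' @export
hit_table <- function(hits = .empty_hits(), query_genome = NA_character_,
                      subject_genome = NA_character_) {
  if (!all(.HIT_COLS %in% names(hits)))
    stop("hit table must have columns: ", paste(.HIT_COLS, collapse = ", "),
         call. = FALSE)
  hits <- hits[.HIT_COLS]
  if (nrow(hits)) {
    if (any(hits$evalue < 0)) stop("negative evalue", call. = FALSE)
    if (any(!is.finite(hits$bitscore))) stop("non-finite bitscore", call. = FALSE)
    if (any(hits$aln_length < 1)) stop("alignment length < 1", call. = FALSE)
  }
  structure(hits, class = c("hit_table", "data.frame"),
            query_genome = query_genome, subject_genome = subject_genome)
}

#' Parse a 12-column tabular homology hit file
#'
#' Reads the NCBI tabular ("outfmt 6") dialect. Every well-formed line
#' becomes a hit; input order is preserved and no e-value threshold is
#' applied. Lines with a column count other than 12, or with non-numeric
#' score fields, raise a parse error naming the line.
#'
#' @param file path or connection to a tab-separated hit file
#' @param query_genome,subject_genome species tags for the two directions
#' @return a [hit_table()]
#' @export
parse_hit_table <- function(file, query_genome = NA_character_,
                            subject_genome = NA_character_) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(hit_table(query_genome = query_genome,
                     subject_genome = subject_genome))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("line ", which(nf != 12L)[1L], ": expected 12 tab-separated columns, found ",
         nf[nf != 12L][1L], call. = FALSE)
  m <- do.call(rbind, parts)
  num <- function(col, what, integerish = FALSE) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L], ": non-numeric ", what, " field",
           call. = FALSE)
    if (integerish) as.integer(v) else v
  }
  df <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "identity"),
    aln_length = num(4, "length", TRUE),
    mismatches = num(5, "mismatch", TRUE),
    gap_opens = num(6, "gapopen", TRUE),
    q_start = num(7, "qstart", TRUE), q_end = num(8, "qend", TRUE),
    s_start = num(9, "sstart", TRUE), s_end = num(10, "send", TRUE),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  hit_table(df, query_genome, subject_genome)
}

#' Write a hit table in the 12-column tabular dialect
#' @param hits a `hit_table`
#' @param file output path
#' @return `hits`, invisibly
#' @export
write_hit_table <- function(hits, file) {
  write.table(as.data.frame(hits)[.HIT_COLS], file, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(hits)
}

# Distinct subject genes of one query, in best-hit order: bitscore
# descending, then evalue ascending, then subject_id; multiple HSPs per
# subject are collapsed to the subject's best HSP first.
.ranked_subjects <- function(hits, query_gene, exclude_self = FALSE) {
  h <- hits[hits$query_id == query_gene, , drop = FALSE]
  if (exclude_self) h <- h[h$subject_id != query_gene, , drop = FALSE]
  if (nrow(h) == 0L) return(character(0))
  h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
  unique(h$subject_id)
}

#' Best hit of a query gene in a hit table
#'
#' Returns the subject gene with the maximal bitscore; ties are broken by
#' smaller e-value, then lexicographically smaller subject id. With
#' `exclude_self`, hits whose subject equals the query gene are removed
#' first (self-hit = identical gene id).
#'
#' @param hits a `hit_table`
#' @param query_gene gene id
#' @param exclude_self drop the query's self-hit before ranking
#' @return subject gene id, or `NA_character_` if the query has no hit
#' @export
best_hit <- function(hits, query_gene, exclude_self = FALSE) {
  r <- .ranked_subjects(hits, query_gene, exclude_self)
  if (length(r) == 0L) NA_character_ else r[[1L]]
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is reported iff b is a's best hit in the A-to-B table and
#' a is b's best hit in the B-to-A table. For the `protein_filtered`
#' channel, pairs whose query/subject sequence-length ratio falls below
#' `length_ratio_min` or above `length_ratio_max` are discarded; the
#' interval is closed, so exact boundary ratios are retained.
#'
#' @param hits_ab,hits_ba `hit_table`s for the two directions
#' @param channel one of `"protein_filtered"`, `"protein"`, `"cds"`
#' @param lengths_a,lengths_b named vectors of sequence lengths on the
#'   channel's sequence type (protein residues or CDS bases); required for
#'   the filtered channel, optional otherwise
#' @param length_ratio_min,length_ratio_max closed filter bounds
#' @return data.frame with columns `gene_a`, `gene_b`, `channel`,
#'   `length_ratio`
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 channel = c("protein_filtered", "protein", "cds"),
                                 lengths_a = NULL, lengths_b = NULL,
                                 length_ratio_min = 0.5,
                                 length_ratio_max = 2.0) {
  channel <- match.arg(channel)
  out <- data.frame(gene_a = character(0), gene_b = character(0),
                    channel = character(0), length_ratio = numeric(0),
                    stringsAsFactors = FALSE)
  queries <- unique(hits_ab$query_id)
  for (a in queries) {
    b <- best_hit(hits_ab, a)
    if (is.na(b)) next
    back <- best_hit(hits_ba, b)
    if (is.na(back) || back != a) next
    ratio <- NA_real_
    if (!is.null(lengths_a) && !is.null(lengths_b)) {
      la <- suppressWarnings(as.numeric(lengths_a[a]))
      lb <- suppressWarnings(as.numeric(lengths_b[b]))
      if (length(la) == 1L && length(lb) == 1L && !is.na(la) && !is.na(lb))
        ratio <- la / lb
    }
    if (channel == "protein_filtered") {
      if (is.na(ratio))
        stop("missing sequence length for pair (", a, ", ", b,
             ") in filtered channel", call. = FALSE)
      if (ratio < length_ratio_min || ratio > length_ratio_max) next
    }
    out <- rbind(out, data.frame(gene_a = a, gene_b = b, channel = channel,
                                 length_ratio = ratio,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Build the anchor pool from the three RBH channels plus syntelogs
#'
#' The anchor pool for one genome pair is the union of partner genes over
#' the length-filtered protein RBH channel, the unfiltered protein channel,
#' the CDS channel, and the syntelog pairs; each anchor records which
#' evidence channels support it.
#'
#' @param rbh_filtered,rbh_protein,rbh_cds data.frames from
#'   [reciprocal_best_hits()] (columns `gene_a`, `gene_b`)
#' @param syntelog_pairs data.frame with columns `gene_a`, `gene_b`
#'   (syntenic partners of reference genes), or `NULL`
#' @param side which side of the pairs to pool (`"b"`: the non-reference
#'   genome, the default; `"a"`: the reference genome)
#' @return data.frame with columns `gene_id` and `evidence`
#'   (comma-separated channel names)
#' @export
build_anchor_pool <- function(rbh_filtered, rbh_protein, rbh_cds,
                              syntelog_pairs = NULL, side = c("b", "a")) {
  side <- match.arg(side)
  col <- if (side == "b") "gene_b" else "gene_a"
  pick <- function(df) if (is.null(df) || nrow(df) == 0L) character(0) else df[[col]]
  chans <- list(protein_filtered = pick(rbh_filtered),
                protein = pick(rbh_protein),
                cds = pick(rbh_cds),
                synteny = pick(syntelog_pairs))
  all_genes <- sort(unique(unlist(chans, use.names = FALSE)))
  evidence <- vapply(all_genes, function(g) {
    paste(names(chans)[vapply(chans, function(v) g %in% v, logical(1))],
          collapse = ",")
  }, character(1))
  data.frame(gene_id = all_genes, evidence = unname(evidence),
             stringsAsFactors = FALSE)
}

#' Forward/reverse expansion screen for family candidates
#'
#' The forward run queries all anchor genes against every genome (no
#' e-value threshold) and collects all subject genes per genome. The
#' reverse run queries each forward-pool candidate back against the
#' reference genome; the candidate's top `reverse_max_targets` distinct
#' reference subjects are kept (best-hit order) before self-hit removal,
#' so a self-hit occupying one slot does not block the other. A candidate
#' is scored into the family iff it is in the forward pool and, after
#' self-hit removal, at least one kept reverse subject belongs to
#' `reference_family`.
#'
#' @param anchors character vector of anchor gene ids (forward-run queries)
#' @param forward_hits named list (by genome tag) of `hit_table`s from the
#'   anchors to each genome
#' @param reverse_hits named list (by genome tag) of `hit_table`s from each
#'   genome's candidates to the reference genome
#' @param reference_family non-empty character vector of reference family
#'   gene ids
#' @param reverse_max_targets reverse-screen target maximum (default 2)
#' @return named list (by genome tag) of candidate gene-id vectors
#' @export
expand_family <- function(anchors, forward_hits, reverse_hits,
                          reference_family, reverse_max_targets = 2L) {
  if (length(reference_family) == 0L)
    stop("reference_family must not be empty", call. = FALSE)
  out <- list()
  for (tag in names(forward_hits)) {
    fh <- forward_hits[[tag]]
    pool <- sort(unique(fh$subject_id[fh$query_id %in% anchors]))
    rh <- reverse_hits[[tag]]
    keep <- vapply(pool, function(cand) {
      subj <- .ranked_subjects(rh, cand)
      kept <- utils::head(subj, reverse_max_targets)
      kept <- setdiff(kept, cand)          # self-hit removal
      any(kept %in% reference_family)
    }, logical(1))
    out[[tag]] <- pool[keep]
  }
  out
}

# ---- built-in seeded aligner -------------------------------------------

.kmer_set <- function(protein, k) {
  n <- nchar(protein)
  if (n < k) return(character(0))
  unique(substring(protein, 1:(n - k + 1L), k:n))
}

#' Deterministic k-mer-seeded local alignment of two proteins
#'
#' Test-time replacement for an external aligner: if the two proteins share
#' at least one exact k-mer, a Smith-Waterman local alignment (BLOSUM62,
#' affine gaps) is computed and reported as a 12-column-style hit; if no
#' k-mer is shared, or the raw score falls below `min_score`, no hit is
#' produced. The reported `bitscore` is the raw alignment score and the
#' e-value is a placeholder 0 (hits are never filtered on e-value).
#'
#' @param query_protein,subject_protein non-empty protein strings
#' @param query_id,subject_id gene ids for the report
#' @param k seed k-mer length
#' @param min_score minimum raw alignment score to report a hit
#' @param gap_opening,gap_extension affine gap penalties
#' @return one-row hit data.frame, or `NULL` when there is no hit
#' @export
seeded_align <- function(query_protein, subject_protein,
                         query_id = "query", subject_id = "subject",
                         k = 5L, min_score = 30,
                         gap_opening = 10, gap_extension = 1) {
  if (!nzchar(query_protein) || !nzchar(subject_protein))
    stop("empty protein sequence", call. = FALSE)
  if (length(intersect(.kmer_set(query_protein, k),
                       .kmer_set(subject_protein, k))) == 0L)
    return(NULL)
  r <- .align_core(toupper(query_protein), toupper(subject_protein),
                   .blosum62(), gap_opening, gap_extension, TRUE)
  if (isTRUE(r$empty) || r$score < min_score) return(NULL)
  .hit_row(r, query_id, subject_id)
}

.hit_row <- function(r, query_id, subject_id) {
  data.frame(
    query_id = query_id, subject_id = subject_id,
    pct_identity = 100 * r$matches / r$aln_length,
    aln_length = r$aln_length, mismatches = r$mismatches,
    gap_opens = r$gap_opens,
    q_start = r$q_start, q_end = r$q_end,
    s_start = r$s_start, s_end = r$s_end,
    evalue = 0, bitscore = r$score, stringsAsFactors = FALSE)
}

# Shared engine for the all-against-all builders: seqs are named character
# vectors; pairs sharing a k-mer are aligned locally with `mat`.
.align_all <- function(seqs_q, seqs_s, queries, k, min_score, mat,
                       gap_opening, gap_extension) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (sid in names(seqs_s))
    for (km in .kmer_set(seqs_s[[sid]], k))
      idx[[km]] <- c(idx[[km]], sid)
  rows <- list()
  for (qid in queries) {
    qseq <- seqs_q[[qid]]
    cand <- unique(unlist(lapply(.kmer_set(qseq, k),
                                 function(km) idx[[km]]), use.names = FALSE))
    if (length(cand) == 0L) next
    for (sid in sort(cand)) {
      r <- .align_core(qseq, seqs_s[[sid]], mat,
                       gap_opening, gap_extension, TRUE)
      if (isTRUE(r$empty) || r$score < min_score) next
      rows[[length(rows) + 1L]] <- .hit_row(r, qid, sid)
    }
  }
  if (length(rows)) do.call(rbind, rows) else .empty_hits()
}

#' All-against-all seeded alignment between two genomes
#'
#' Builds a `hit_table` by running the seeded local aligner for every gene
#' pair that shares at least one protein k-mer (a k-mer index keeps the
#' search near-linear for unrelated sequences). For a self-comparison,
#' self-hits are included; downstream operations remove them where
#' required.
#'
#' @param ann_q,ann_s `genome_annotation`s for query and subject genome
#' @param queries optional subset of query gene ids (default: all)
#' @param k,min_score,gap_opening,gap_extension see [seeded_align()]
#' @return a [hit_table()]
#' @export
align_genomes <- function(ann_q, ann_s, queries = NULL, k = 5L,
                          min_score = 30, gap_opening = 10,
                          gap_extension = 1) {
  if (is.null(queries)) queries <- ann_q$genes$gene_id
  hits <- .align_all(ann_q$protein, ann_s$protein, queries, k, min_score,
                     .blosum62(), gap_opening, gap_extension)
  hit_table(hits, ann_q$species_tag, ann_s$species_tag)
}
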