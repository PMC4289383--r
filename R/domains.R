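.KNOWN_DOMAINS <- c("NB-ARC", "LRR", "TIR")

#' Load multi-predictor domain calls from a TSV file
#'
#' Expects the tab-separated predictor dialect
#' `gene_id<TAB>predictor<TAB>domain_label<TAB>start<TAB>end<TAB>score`
#' (a header line is detected and skipped; score may be `NA`). Domain
#' labels other than `NB-ARC`, `LRR`, `TIR` are mapped to `other:<raw>`.
#' Identical duplicate rows are collapsed.
#'
#' @param file path or connection
#' @param protein_lengths optional named vector of protein lengths; when
#'   supplied, calls whose coordinates exceed the gene's protein length are
#'   a validation error
#' @return data.frame with columns `gene_id`, `predictor`, `domain_label`,
#'   `start`, `end`, `score`
#' @export
load_domain_calls <- function(file, protein_lengths = NULL) {
  df <- read.table(file, sep = "\t", header = FALSE, quote = "",
                   stringsAsFactors = FALSE,
                   col.names = c("gene_id", "predictor", "domain_label",
                                 "start", "end", "score"),
                   colClasses = c("character", "character", "character",
                                  "character", "character", "character"))
  if (nrow(df) && identical(tolower(df$start[1]), "start"))
    df <- df[-1L, , drop = FALSE]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$score <- suppressWarnings(as.numeric(df$score))
  domain_calls(df, protein_lengths)
}

#' Validate and normalize a table of domain calls
#' @param df data.frame with columns `gene_id`, `predictor`,
#'   `domain_label`, `start`, `end`, and optionally `score`
#' @param protein_lengths optional named vector of protein lengths
#' @return normalized data.frame of domain calls
#' @export
domain_calls <- function(df, protein_lengths = NULL) {
  if (is.null(df$score)) df$score <- NA_real_
  if (any(is.na(df$start) | is.na(df$end)))
    stop("domain call with missing coordinates", call. = FALSE)
  if (any(df$end < df$start))
    stop("domain call with end < start (gene ",
         df$gene_id[which(df$end < df$start)[1L]], ")", call. = FALSE)
  if (any(df$start < 1L))
    stop("domain call with start < 1", call. = FALSE)
  known <- df$domain_label %in% .KNOWN_DOMAINS
  df$domain_label[!known] <- paste0("other:", df$domain_label[!known])
  if (!is.null(protein_lengths)) {
    plen <- protein_lengths[df$gene_id]
    bad <- !is.na(plen) & df$end > plen
    if (any(bad))
      stop("domain call beyond protein length for gene ",
           df$gene_id[which(bad)[1L]], call. = FALSE)
  }
  df <- unique(df)
  df <- df[order(df$gene_id, df$domain_label, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Consensus domain architecture per gene
#'
#' Union rule over predictors: a domain counts as present when at least
#' `min_predictors` distinct predictors report it (default 1, i.e. any
#' predictor). A gene is a family member iff all `required_domains` are
#' present (`NB-ARC` and at least one `LRR` repeat call by default).
#' Family members are subclassified `TNL` when a TIR domain is present,
#' else `NL`; non-members get no subclass.
#'
#' @param calls data.frame of domain calls (see [domain_calls()])
#' @param genes optional character vector of genes to report (genes without
#'   calls are reported as non-members)
#' @param required_domains domain labels all required for membership
#' @param min_predictors distinct-predictor threshold per domain
#' @return data.frame with columns `gene_id`, `domains_present`
#'   (comma-separated), `family_member`, `subclass`
#' @export
consensus_architecture <- function(calls, genes = NULL,
                                   required_domains = c("NB-ARC", "LRR"),
                                   min_predictors = 1L) {
  if (is.null(genes)) genes <- sort(unique(calls$gene_id))
  rows <- lapply(genes, function(g) {
    sub <- calls[calls$gene_id == g, , drop = FALSE]
    tab <- tapply(sub$predictor, sub$domain_label,
                  function(p) length(unique(p)))
    present <- names(tab)[tab >= min_predictors]
    member <- all(required_domains %in% present)
    subclass <- if (!member) NA_character_
                else if ("TIR" %in% present) "TNL" else "NL"
    data.frame(gene_id = g,
               domains_present = paste(sort(present), collapse = ","),
               family_member = member, subclass = subclass,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Venn-region counts for the three main domains
#'
#' Counts the seven regions of the NB-ARC/LRR/TIR Venn diagram for one
#' genome, plus the family count `|NB-ARC intersect LRR|` and the union
#' size.
#'
#' @param nbarc,lrr,tir character vectors of gene ids carrying each domain
#' @return named numeric vector with elements `nbarc_only`, `lrr_only`,
#'   `tir_only`, `nbarc_lrr_only`, `nbarc_tir_only`, `lrr_tir_only`,
#'   `all_three`, `family` (NB-ARC and LRR regardless of TIR), `union`
#' @export
venn_counts <- function(nbarc, lrr, tir = character(0)) {
  nbarc <- unique(nbarc); lrr <- unique(lrr); tir <- unique(tir)
  all_genes <- union(union(nbarc, lrr), tir)
  a <- all_genes %in% nbarc
  b <- all_genes %in% lrr
  c_ <- all_genes %in% tir
  c(nbarc_only = sum(a & !b & !c_),
    lrr_only = sum(!a & b & !c_),
    tir_only = sum(!a & !b & c_),
    nbarc_lrr_only = sum(a & b & !c_),
    nbarc_tir_only = sum(a & !b & c_),
    lrr_tir_only = sum(!a & b & c_),
    all_three = sum(a & b & c_),
    family = sum(a & b),
    union = length(all_genes))
}

#' Planted motif strings recognized by the toy annotator
#'
#' These fixed amino-acid signatures stand in for HMM domain models in
#' synthetic data: an NB-ARC P-loop-like signature, one LRR repeat unit,
#' and a TIR-like signature. The synthetic-clade generator plants them and
#' [toy_annotate()] detects them by exact substring match.
#'
#' @return named list with elements `nbarc`, `lrr`, `tir`
#' @export
famscape_motifs <- function() {
  list(nbarc = "GMGGVGKTT", lrr = "LDLSHNNLS", tir = "FLSFRGEDT")
}

#' Toy motif annotator for synthetic proteins
#'
#' Deterministic fixture stand-in for HMM domain predictors: emits one
#' NB-ARC (or TIR) call when the planted signature substring occurs, and
#' one LRR call per occurrence of the planted repeat motif.
#'
#' @param protein non-empty protein string
#' @param gene_id gene id for the report
#' @return data.frame of domain calls (possibly 0 rows)
#' @export
toy_annotate <- function(protein, gene_id = "gene") {
  if (!nzchar(protein)) stop("empty protein", call. = FALSE)
  motifs <- famscape_motifs()
  find_all <- function(motif) {
    hits <- gregexpr(motif, protein, fixed = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }
  rows <- list()
  add <- function(label, starts, width) {
    for (s in starts)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = gene_id, predictor = "toy", domain_label = label,
        start = s, end = s + width - 1L, score = NA_real_,
        stringsAsFactors = FALSE)
  }
  add("NB-ARC", find_all(motifs$nbarc), nchar(motifs$nbarc))
  add("LRR", find_all(motifs$lrr), nchar(motifs$lrr))
  add("TIR", find_all(motifs$tir), nchar(motifs$tir))
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), predictor = character(0),
                      domain_label = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  domain_calls(do.call(rbind, rows))
}
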