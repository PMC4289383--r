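#' @useDynLib famscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif setNames sd
#' @importFrom utils read.table write.table
NULL

# BLOSUM62 substitution matrix (from Biostrings), cached.
.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Simple nucleotide substitution matrix over ACGTN (N neutral).
.dna_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# Standard genetic code, keyed by codon (from Biostrings).
.genetic_code <- function() Biostrings::GENETIC_CODE

.stop_codons <- function() names(.genetic_code())[.genetic_code() == "*"]

#' Split a DNA string into codons
#'
#' @param cds a single DNA string whose length is a multiple of 3
#' @return character vector of codons
#' @keywords internal
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence under the standard genetic code
#'
#' Terminal stop codons are retained as `*`; use [strip_terminal_stop()]
#' beforehand to drop them.
#'
#' @param cds DNA string, length a multiple of 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  codons <- toupper(split_codons(cds))
  gc <- .genetic_code()
  aa <- gc[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("unrecognized codon '", codons[bad], "' at codon position ", bad,
         call. = FALSE)
  }
  paste(aa, collapse = "")
}

#' Remove a terminal stop codon from a CDS, if present
#' @param cds DNA string
#' @return DNA string without the trailing stop codon
#' @export
strip_terminal_stop <- function(cds) {
  n <- nchar(cds)
  if (n >= 3L && n %% 3L == 0L) {
    last <- toupper(substr(cds, n - 2L, n))
    if (last %in% .stop_codons()) return(substr(cds, 1L, n - 3L))
  }
  cds
}

# Round half away from zero (report-table convention; R's round() is
# round-half-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream of sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 48271 + seq_len(n) * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
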