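## Nei-Gojobori (1986) Ka/Ks on pairwise codon alignments:
## approximate-method site counting with equal-weight pathway averaging and
## Jukes-Cantor (1969) multiple-hit correction.

.BASES <- c("A", "C", "G", "T")

# All 9 single-base mutants of a codon.
.codon_mutants <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(.BASES, substr(codon, pos, pos))) {
      m <- codon
      substr(m, pos, pos) <- b
      out <- c(out, m)
    }
  }
  out
}

# Cache of per-codon synonymous site counts over the 61 sense codons.
.ng86_cache <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- .genetic_code()
    sense <- names(gc)[gc != "*"]
    s <- setNames(numeric(length(sense)), sense)
    for (codon in sense) {
      total <- 0
      for (pos in 1:3) {
        alts <- vapply(setdiff(.BASES, substr(codon, pos, pos)),
                       function(b) { m <- codon; substr(m, pos, pos) <- b; m },
                       character(1))
        aa <- gc[alts]
        keep <- aa != "*"              # mutations to stops excluded
        if (any(keep))
          total <- total + sum(aa[keep] == gc[[codon]]) / sum(keep)
      }
      s[codon] <- total
    }
    cache <<- s
    cache
  }
})

#' NG86 synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the fraction of the three possible single-base
#' mutations that are synonymous is accumulated into the synonymous site
#' count S; mutations creating stop codons are excluded from the
#' denominator at that position. N is defined as `3 - S`.
#'
#' @param codon one of the 61 sense codons (upper case, `ACGT` alphabet)
#' @return named numeric vector `c(S = ..., N = ...)`
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("not an unambiguous codon: '", codon, "'", call. = FALSE)
  if (.genetic_code()[[codon]] == "*")
    stop("stop codon '", codon, "' has no site counts", call. = FALSE)
  s <- .ng86_cache()[[codon]]
  c(S = s, N = 3 - s)
}

# All permutations of 1..n (n <= 3 here).
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}

# Pathway-averaged synonymous/nonsynonymous difference counts between two
# sense codons. Orderings passing through a stop codon are excluded from
# the average; returns NULL if no stop-free ordering exists.
.ng86_diff_counts <- function(c1, c2) {
  gc <- .genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  sd_tot <- 0; nd_tot <- 0; n_paths <- 0L
  for (ord in .perms(pos)) {
    cur <- c1
    sd_p <- 0; nd_p <- 0
    ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (ok) {
      sd_tot <- sd_tot + sd_p
      nd_tot <- nd_tot + nd_p
      n_paths <- n_paths + 1L
    }
  }
  if (n_paths == 0L) return(NULL)
  c(sd = sd_tot / n_paths, nd = nd_tot / n_paths)
}

# Full 64x64 pathway-averaged difference-count matrices (SD, ND), indexed
# by codon; NA where either codon is a stop or every ordering crosses a
# stop codon. Computed once per session.
.pairwise_counts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- .genetic_code()
    codons <- names(gc)
    SD <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
    ND <- SD
    for (i in seq_along(codons)) {
      if (gc[[codons[i]]] == "*") next
      for (j in seq_along(codons)) {
        if (gc[[codons[j]]] == "*") next
        d <- .ng86_diff_counts(codons[i], codons[j])
        if (!is.null(d)) {
          SD[i, j] <- d[["sd"]]
          ND[i, j] <- d[["nd"]]
        }
      }
    }
    cache <<- list(SD = SD, ND = ND)
    cache
  }
})

.ng86_diff_memo <- function(c1, c2) {
  pc <- .pairwise_counts()
  sd <- pc$SD[c1, c2]
  if (is.na(sd)) return(NULL)
  c(sd = sd, nd = pc$ND[c1, c2])
}

#' Construct a validated pairwise codon alignment
#'
#' Two gap-aligned CDS strings of equal length divisible by 3, with gaps
#' only in whole-codon (`---`) units. Removing the gaps must recover each
#' input CDS exactly; that property is guaranteed by [backtranslate()].
#'
#' @param cds1,cds2 gap-aligned CDS strings
#' @return object of class `codon_alignment`
#' @export
codon_alignment <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2))
    stop("aligned CDS strings differ in length", call. = FALSE)
  if (nchar(cds1) %% 3L != 0L)
    stop("aligned length not divisible by 3", call. = FALSE)
  for (s in list(cds1, cds2)) {
    codons <- split_codons(s)
    partial <- grepl("-", codons) & codons != "---"
    if (any(partial))
      stop("gaps must come in whole-codon units (codon ",
           which(partial)[1L], ")", call. = FALSE)
  }
  structure(list(cds1 = toupper(cds1), cds2 = toupper(cds2)),
            class = "codon_alignment")
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Codon columns with a gap or an ambiguous base in either sequence are
#' excluded pairwise. Site counts S and N are averaged over the two
#' sequences; difference counts use equal-weight averaging over all
#' substitution orderings that avoid stop-codon intermediates (columns
#' where every ordering is excluded are skipped entirely). Proportions are
#' corrected for multiple hits with the Jukes-Cantor formula
#' `K = -(3/4) log(1 - 4p/3)`; saturated proportions (`p >= 3/4`) give an
#' undefined (NA) rate. `omega = Ka/Ks` is defined only when `Ks > 0`.
#'
#' @param aln a [codon_alignment()]
#' @return object of class `substitution_rates`: list with `S`, `N`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ka`, `Ks`, `omega`, `n_codons` (compared columns)
#' @export
kaks_pairwise <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  gc <- .genetic_code()
  cod1 <- split_codons(aln$cds1)
  cod2 <- split_codons(aln$cds2)
  sites <- .ng86_cache()
  pc <- .pairwise_counts()
  comparable <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2)
  c1 <- cod1[comparable]; c2 <- cod2[comparable]
  is_stop <- gc[c1] == "*" | gc[c2] == "*"
  if (any(is_stop))
    stop("stop codon in ungapped alignment column ",
         which(comparable)[which(is_stop)[1L]], call. = FALSE)
  sd_col <- pc$SD[cbind(c1, c2)]
  keep <- !is.na(sd_col)               # NA: all pathways cross a stop codon
  n_codons <- sum(keep)
  if (n_codons == 0L)
    stop("no comparable codon sites in alignment", call. = FALSE)
  s_col <- (sites[c1[keep]] + sites[c2[keep]]) / 2
  S <- sum(s_col)
  N <- sum(3 - s_col)
  Sd <- sum(sd_col[keep])
  Nd <- sum(pc$ND[cbind(c1, c2)][keep])
  ps <- Sd / S
  pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps)
  Ka <- jc(pn)
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ka = Ka, Ks = Ks, omega = omega, n_codons = n_codons),
            class = "substitution_rates")
}

#' @export
print.substitution_rates <- function(x, ...) {
  cat(sprintf(
    "substitution_rates: %d codons; S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s omega=%s\n",
    x$n_codons, x$S, x$N, x$Sd, x$Nd,
    format(x$Ka, digits = 4), format(x$Ks, digits = 4),
    format(x$omega, digits = 4)))
  invisible(x)
}

#' Global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gaps (a gap of length L
#' costs `gap_opening + L * gap_extension`) and a standard substitution
#' matrix (BLOSUM62 by default). Ties are broken deterministically,
#' preferring a residue pairing over a gap in the second sequence over a
#' gap in the first.
#'
#' @param p1,p2 protein strings (non-empty)
#' @param substitution_matrix scoring matrix with single-letter dimnames
#'   (default: BLOSUM62 from Biostrings)
#' @param gap_opening,gap_extension positive penalties
#' @return list with gapped strings `a1`, `a2` and the alignment `score`
#' @export
align_protein_pair <- function(p1, p2, substitution_matrix = NULL,
                               gap_opening = 10, gap_extension = 1) {
  if (!nzchar(p1) || !nzchar(p2))
    stop("empty protein sequence", call. = FALSE)
  mat <- substitution_matrix %||% .blosum62()
  r <- .align_core(toupper(p1), toupper(p2), mat,
                   gap_opening, gap_extension, FALSE)
  list(a1 = r$a1, a2 = r$a2, score = r$score)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned residue back to its source codon and each protein gap
#' to a `---` codon gap (pal2nal semantics). Terminal stop codons are
#' stripped from the CDS before mapping. A residue whose codon does not
#' translate to it is a hard error naming the residue position.
#'
#' @param aln list with gapped protein strings `a1`, `a2` (as returned by
#'   [align_protein_pair()])
#' @param cds1,cds2 the unaligned coding sequences of the two proteins
#' @return a [codon_alignment()]
#' @export
backtranslate <- function(aln, cds1, cds2) {
  map_one <- function(gapped, cds, which_seq) {
    cds <- strip_terminal_stop(toupper(cds))
    codons <- split_codons(cds)
    chars <- strsplit(gapped, "")[[1]]
    n_res <- sum(chars != "-")
    if (n_res != length(codons))
      stop("sequence ", which_seq, ": alignment has ", n_res,
           " residues but CDS encodes ", length(codons), call. = FALSE)
    gc <- .genetic_code()
    out <- character(length(chars))
    j <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") { out[i] <- "---"; next }
      j <- j + 1L
      aa <- gc[[codons[j]]]
      if (is.na(aa) || aa != chars[i])
        stop("sequence ", which_seq, ": codon ", codons[j],
             " does not encode aligned residue '", chars[i],
             "' at residue position ", j, call. = FALSE)
      out[i] <- codons[j]
    }
    paste(out, collapse = "")
  }
  if (nchar(aln$a1) == 0L && nchar(aln$a2) == 0L)
    return(codon_alignment("", ""))
  codon_alignment(map_one(aln$a1, cds1, 1L), map_one(aln$a2, cds2, 2L))
}

#' Align two genes and estimate their substitution rates
#'
#' Convenience wrapper: global protein alignment, back-translation to a
#' codon alignment, then NG86 Ka/Ks. Optionally restricts the analysis to
#' codon columns whose residue in the first gene falls inside supplied
#' amino-acid ranges (e.g. NB-ARC and LRR domain blocks).
#'
#' @param ann a `genome_annotation` holding both genes
#' @param gene_a,gene_b gene ids
#' @param regions optional data.frame with columns `start`, `end` (1-based
#'   amino-acid positions on `gene_a`'s protein) to restrict the analysis
#' @return a `substitution_rates` object
#' @export
rates_for_pair <- function(ann, gene_a, gene_b, regions = NULL) {
  p1 <- ann$protein[[gene_a]]
  p2 <- ann$protein[[gene_b]]
  aln <- align_protein_pair(p1, p2)
  if (!is.null(regions) && nrow(regions) > 0) {
    keep_res <- rep(FALSE, nchar(p1))
    for (i in seq_len(nrow(regions)))
      keep_res[seq(regions$start[i], min(regions$end[i], nchar(p1)))] <- TRUE
    ch1 <- strsplit(aln$a1, "")[[1]]
    ch2 <- strsplit(aln$a2, "")[[1]]
    res1 <- cumsum(ch1 != "-")
    res2 <- cumsum(ch2 != "-")
    keep_col <- ch1 != "-" & keep_res[pmax(res1, 1L)]
    sliced <- list(a1 = paste(ch1[keep_col], collapse = ""),
                   a2 = paste(ch2[keep_col], collapse = ""))
    cds1 <- .slice_cds(ann$cds[[gene_a]], res1[keep_col])
    cds2 <- .slice_cds(ann$cds[[gene_b]], res2[keep_col & ch2 != "-"])
    return(kaks_pairwise(backtranslate(sliced, cds1, cds2)))
  }
  kaks_pairwise(backtranslate(aln, ann$cds[[gene_a]], ann$cds[[gene_b]]))
}

# Extract the codons of the given residue indices from a CDS.
.slice_cds <- function(cds, residues) {
  codons <- split_codons(strip_terminal_stop(toupper(cds)))
  paste(codons[residues], collapse = "")
}

#' Summarize Ka/Ks by duplicate class
#'
#' @param rates data.frame with at least columns `class` and `omega`
#'   (per-pair NG86 estimates; `NA` omega = undefined)
#' @param test if `TRUE`, adds pairwise Wilcoxon rank-sum p-values between
#'   classes (reported, never used as a filter)
#' @return data.frame with one row per class: `class`, `n_pairs`,
#'   `n_defined`, `mean_omega`, `sd_omega`; optionally an attribute
#'   `"tests"` with the pairwise test table
#' @export
summarize_class_rates <- function(rates, test = FALSE) {
  classes <- unique(rates$class)
  out <- do.call(rbind, lapply(classes, function(cl) {
    om <- rates$omega[rates$class == cl]
    def <- om[!is.na(om)]
    data.frame(class = cl, n_pairs = length(om), n_defined = length(def),
               mean_omega = if (length(def)) mean(def) else NA_real_,
               sd_omega = if (length(def) > 1) sd(def) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (test && length(classes) > 1) {
    combs <- utils::combn(classes, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(combs, function(pr) {
      x <- rates$omega[rates$class == pr[1] & !is.na(rates$omega)]
      y <- rates$omega[rates$class == pr[2] & !is.na(rates$omega)]
      p <- if (length(x) && length(y))
        suppressWarnings(stats::wilcox.test(x, y)$p.value) else NA_real_
      data.frame(class_a = pr[1], class_b = pr[2], p_value = p,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "tests") <- tests
  }
  out
}

# Best within-pool partner of `gene`: highest-bitscore non-self hit whose
# subject lies in `pool` (best-hit ordering).
.best_pool_hit <- function(hits, gene, pool) {
  subj <- .ranked_subjects(hits, gene, exclude_self = TRUE)
  subj <- subj[subj %in% pool]
  if (length(subj) == 0L) NA_character_ else subj[[1L]]
}

# Highest bitscore linking two genes, in either direction.
.pair_score <- function(hits, a, b) {
  s <- hits$bitscore[(hits$query_id == a & hits$subject_id == b) |
                       (hits$query_id == b & hits$subject_id == a)]
  if (length(s) == 0L) -Inf else max(s)
}

#' Select the sequence pairs compared per duplicate class
#'
#' Pairing rules, per class: tandem arrays contribute the pair of their
#' first and last member by start coordinate; each ohnolog gene is paired
#' with its best non-self hit restricted to the species' ohnolog pool, with
#' triplet groups contributing only their highest-scoring pair; each
#' singleton is paired with its best non-self hit among all family genes of
#' the species (skipped with a warning when it has none). Duplicate
#' unordered pairs are collapsed.
#'
#' @param labels data.frame from [classify_duplicates()]
#' @param arrays list of tandem arrays for the species
#' @param ohnolog_groups data.frame from [assign_ohnolog_groups()] (or NULL)
#' @param hits within-species `hit_table`
#' @return data.frame with columns `gene_a`, `gene_b`, `class`
#' @export
select_class_pairs <- function(labels, arrays, ohnolog_groups, hits) {
  rows <- list()
  add <- function(a, b, cl) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_a = min(a, b), gene_b = max(a, b), class = cl,
      stringsAsFactors = FALSE)
  }
  # tandem: first vs last array member by coordinate
  for (arr in arrays) {
    m <- arr$members
    if (length(m) >= 2L) add(m[1L], m[length(m)], "tandem")
  }
  # ohnolog: best non-self hit within the species' ohnolog pool
  pool <- labels$gene_id[labels$is_ohnolog]
  ohno_pairs <- list()
  for (g in pool) {
    p <- .best_pool_hit(hits, g, setdiff(pool, g))
    if (!is.na(p))
      ohno_pairs[[length(ohno_pairs) + 1L]] <-
        c(min(g, p), max(g, p))
  }
  ohno_pairs <- unique(ohno_pairs)
  # triplets (and larger flagged groups): keep only the highest-scoring pair
  if (!is.null(ohnolog_groups) && nrow(ohnolog_groups)) {
    for (gid in unique(ohnolog_groups$group_id[ohnolog_groups$size >= 3L])) {
      members <- ohnolog_groups$gene_id[ohnolog_groups$group_id == gid]
      inside <- vapply(ohno_pairs, function(pr)
        all(pr %in% members), logical(1))
      if (sum(inside) > 1L) {
        scores <- vapply(ohno_pairs[inside], function(pr)
          .pair_score(hits, pr[1L], pr[2L]), numeric(1))
        drop <- which(inside)[-which.max(scores)]
        ohno_pairs <- ohno_pairs[-drop]
      }
    }
  }
  for (pr in ohno_pairs) add(pr[1L], pr[2L], "ohnolog")
  # singleton: best non-self hit among all family genes of the species
  family <- labels$gene_id
  for (g in labels$gene_id[labels$klass == "singleton"]) {
    p <- .best_pool_hit(hits, g, setdiff(family, g))
    if (is.na(p)) {
      warning("singleton ", g, " has no within-species family hit; skipped")
      next
    }
    add(g, p, "singleton")
  }
  if (length(rows) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
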