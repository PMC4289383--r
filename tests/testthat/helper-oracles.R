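# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately share no code with the package
# internals beyond the public genetic code table.

# ---- reciprocal best hits ------------------------------------------------
# Score/evalue matrices with genes as dimnames; best hit by bitscore, then
# smaller evalue, then lexicographically smaller subject.
oracle_best <- function(scores, evalues, query) {
  subj <- colnames(scores)
  s <- scores[query, ]
  e <- evalues[query, ]
  ok <- !is.na(s)
  if (!any(ok)) return(NA_character_)
  ord <- order(-s[ok], e[ok], subj[ok])
  subj[ok][ord][1L]
}

oracle_rbh <- function(scores_ab, evalues_ab, scores_ba, evalues_ba,
                       len_a = NULL, len_b = NULL, ratio = NULL) {
  out <- list()
  for (a in rownames(scores_ab)) {
    b <- oracle_best(scores_ab, evalues_ab, a)
    if (is.na(b)) next
    if (!identical(oracle_best(scores_ba, evalues_ba, b), a)) next
    if (!is.null(ratio)) {
      r <- len_a[[a]] / len_b[[b]]
      if (r < ratio[1] || r > ratio[2]) next
    }
    out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

# ---- collinear chaining --------------------------------------------------
# Exhaustive enumeration over all subsets of <= ~12 pairs, replicating the
# documented tie rules: max pair count, then smaller start rank_x, then
# start rank_y, then orientation "same", then lexicographic pair sequence.
oracle_valid_chain <- function(sub, max_gap) {
  sub <- sub[order(sub$rank_x, sub$rank_y), , drop = FALSE]
  n <- nrow(sub)
  if (n == 1L) return(list(ok = TRUE, orientation = "same", sub = sub))
  dx <- diff(sub$rank_x)
  dy <- diff(sub$rank_y)
  if (any(dx <= 0) || any(dx > max_gap)) return(list(ok = FALSE))
  for (orient in c(1, -1)) {
    d <- orient * dy
    if (all(d > 0) && all(d <= max_gap))
      return(list(ok = TRUE,
                  orientation = if (orient == 1) "same" else "inverted",
                  sub = sub))
  }
  list(ok = FALSE)
}

oracle_chain_key <- function(ch) {
  c(-nrow(ch$sub), ch$sub$rank_x[1L], ch$sub$rank_y[1L],
    ch$orientation != "same", as.vector(rbind(ch$sub$rank_x, ch$sub$rank_y)))
}

oracle_key_less <- function(a, b) {
  k <- min(length(a), length(b))
  for (i in seq_len(k)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

oracle_best_chain <- function(pairs, max_gap) {
  n <- nrow(pairs)
  best <- NULL; best_key <- NULL; best_rows <- NULL
  for (mask in seq_len(2^n - 1L)) {
    rows <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    ch <- oracle_valid_chain(pairs[rows, , drop = FALSE], max_gap)
    if (!ch$ok) next
    key <- oracle_chain_key(ch)
    if (is.null(best) || oracle_key_less(key, best_key)) {
      best <- ch; best_key <- key; best_rows <- rows
    }
  }
  list(chain = best, rows = best_rows)
}

oracle_chain_blocks <- function(pairs, max_gap, min_size) {
  pairs <- unique(pairs)
  blocks <- list()
  remaining <- pairs
  while (nrow(remaining) > 0L) {
    b <- oracle_best_chain(remaining, max_gap)
    if (is.null(b$chain) || nrow(b$chain$sub) < min_size) break
    blocks[[length(blocks) + 1L]] <-
      list(pairs = b$chain$sub, orientation = b$chain$orientation)
    remaining <- remaining[-b$rows, , drop = FALSE]
  }
  blocks
}

# ---- alignment -----------------------------------------------------------
# Exhaustive global alignment score with affine gaps (gap of length L
# costs open + L * ext): plain recursion over the three edit operations,
# tracking the previous operation for affine accounting.
oracle_global_score <- function(s1, s2, mat, open, ext) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  rec2 <- function(i, j, prev) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, mat[a[i], b[j]] + rec2(i + 1L, j + 1L, "M"))
    if (i <= length(a)) {
      cost <- if (identical(prev, "X")) ext else open + ext
      best <- max(best, -cost + rec2(i + 1L, j, "X"))
    }
    if (j <= length(b)) {
      cost <- if (identical(prev, "Y")) ext else open + ext
      best <- max(best, -cost + rec2(i, j + 1L, "Y"))
    }
    best
  }
  rec2(1L, 1L, NULL)
}

# Exhaustive local score: best global score over all substring pairs
# (empty alignment scores 0).
oracle_local_score <- function(s1, s2, mat, open, ext) {
  n <- nchar(s1); m <- nchar(s2)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    sc <- oracle_global_score(substr(s1, i1, i2), substr(s2, j1, j2),
                              mat, open, ext)
    if (sc > best) best <- sc
  }
  best
}

# ---- NG86 ----------------------------------------------------------------
# Second, independent NG86 implementation: explicit site enumeration and
# explicit path enumeration for 1-3 differences.
oracle_ng86 <- function(cds1, cds2) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codon_sites <- function(cd) {
    syn <- 0
    for (p in 1:3) {
      alts <- setdiff(bases, substr(cd, p, p))
      tot <- 0; s <- 0
      for (b in alts) {
        m <- cd; substr(m, p, p) <- b
        if (code[[m]] == "*") next
        tot <- tot + 1
        if (code[[m]] == code[[cd]]) s <- s + 1
      }
      if (tot > 0) syn <- syn + s / tot
    }
    syn
  }
  all_orders <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (k in seq_along(v))
      for (rest in all_orders(v[-k])) res <- c(res, list(c(v[k], rest)))
    res
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq(1, nchar(cds1), 3)) {
    c1 <- substr(cds1, k, k + 2)
    c2 <- substr(cds2, k, k + 2)
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    paths <- 0; sdp <- 0; ndp <- 0
    for (ord in all_orders(pos)) {
      cur <- c1; sdd <- 0; ndd <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        if (code[[nxt]] == "*") { ok <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) sdd <- sdd + 1 else ndd <- ndd + 1
        cur <- nxt
      }
      if (ok) { paths <- paths + 1; sdp <- sdp + sdd; ndp <- ndp + ndd }
    }
    if (length(pos) > 0 && paths == 0) next   # column skipped
    s_c <- (codon_sites(c1) + codon_sites(c2)) / 2
    S <- S + s_c; N <- N + 3 - s_c
    if (paths > 0) { Sd <- Sd + sdp / paths; Nd <- Nd + ndp / paths }
  }
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(ps), Ka = jc(pn))
}

# ---- Venn ----------------------------------------------------------------
oracle_venn <- function(a, b, c3) {
  u <- unique(c(a, b, c3))
  tup <- table(factor(paste0(
    as.integer(u %in% a), as.integer(u %in% b), as.integer(u %in% c3)),
    levels = c("100", "010", "001", "110", "101", "011", "111")))
  c(nbarc_only = unname(tup["100"]), lrr_only = unname(tup["010"]),
    tir_only = unname(tup["001"]), nbarc_lrr_only = unname(tup["110"]),
    nbarc_tir_only = unname(tup["101"]), lrr_tir_only = unname(tup["011"]),
    all_three = unname(tup["111"]),
    family = sum(u %in% a & u %in% b), union = length(u))
}

# ---- fixture builders ----------------------------------------------------
# Random protein alphabet (standard residues only).
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# Random CDS of n codons (sense codons, starts with ATG, no stop).
random_sense_cds <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*" ]
  paste(c("ATG", sample(setdiff(sense, "ATG"), n - 1L, TRUE)),
        collapse = "")
}

# Tiny genome: genes at given starts on given seqs, with consistent
# random CDS/protein sequences.
tiny_genome <- function(tag, seq_id, start, gene_id = NULL, codons = 20L) {
  n <- length(start)
  if (is.null(gene_id)) gene_id <- sprintf("%s_g%02d", tag, seq_len(n))
  cds <- vapply(seq_len(n), function(i) random_sense_cds(codons),
                character(1))
  protein <- vapply(cds, famscape::translate_cds, character(1))
  genome_annotation(
    tag,
    data.frame(gene_id = gene_id, seq_id = seq_id, start = start,
               end = start + nchar(cds) - 1L, strand = "+",
               stringsAsFactors = FALSE),
    setNames(cds, gene_id), setNames(protein, gene_id))
}

# Hit table from a compact data.frame of (query, subject, bitscore[,evalue]).
quick_hits <- function(df, qg = "A", sg = "B") {
  n <- nrow(df)
  hit_table(data.frame(
    query_id = df$query, subject_id = df$subject,
    pct_identity = 90, aln_length = 100L, mismatches = 5L, gap_opens = 0L,
    q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
    evalue = if (is.null(df$evalue)) rep(0, n) else df$evalue,
    bitscore = df$bitscore, stringsAsFactors = FALSE), qg, sg)
}
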