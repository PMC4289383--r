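test_that("parse_hit_table handles the 12-column dialect strictly", {
  line <- "q1\ts1\t95.5\t100\t4\t1\t1\t100\t1\t100\t1e-50\t200"
  f <- withr::local_tempfile(lines = line)
  h <- parse_hit_table(f, "A", "B")
  expect_equal(nrow(h), 1L)
  expect_equal(h$bitscore, 200)
  expect_equal(h$evalue, 1e-50)

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(parse_hit_table(empty)), 0L)

  bad <- withr::local_tempfile(
    lines = c(line, "q2\ts2\t90\t50\t5\t0\t1\t50\t1\t50\t0"))
  expect_error(parse_hit_table(bad), "line 2.*12")

  nonnum <- withr::local_tempfile(
    lines = "q1\ts1\t95.5\t100\t4\t1\t1\t100\t1\t100\t1e-50\tabc")
  expect_error(parse_hit_table(nonnum), "non-numeric")
})

test_that("hit tables survive a write/parse round trip in input order", {
  df <- data.frame(query = c("q2", "q1"), subject = c("s1", "s2"),
                   bitscore = c(50, 100))
  h <- quick_hits(df)
  f <- withr::local_tempfile()
  write_hit_table(h, f)
  back <- parse_hit_table(f, "A", "B")
  expect_equal(back$query_id, c("q2", "q1"))
  expect_equal(back$bitscore, c(50, 100))
})

test_that("best_hit ranks by bitscore, then evalue, then subject id", {
  h <- quick_hits(data.frame(query = "q", subject = c("s1", "s2"),
                             bitscore = c(90, 100)))
  expect_equal(best_hit(h, "q"), "s2")
  h2 <- quick_hits(data.frame(query = "q", subject = c("sA", "sB"),
                              bitscore = c(100, 100),
                              evalue = c(1e-40, 1e-50)))
  expect_equal(best_hit(h2, "q"), "sB")
  h3 <- quick_hits(data.frame(query = "q", subject = c("sB", "sA"),
                              bitscore = c(100, 100), evalue = c(0, 0)))
  expect_equal(best_hit(h3, "q"), "sA")
  h4 <- quick_hits(data.frame(query = "q", subject = "q", bitscore = 500))
  expect_true(is.na(best_hit(h4, "q", exclude_self = TRUE)))
})

test_that("reciprocal best hits require mutual best and honor the closed length window", {
  ab <- quick_hits(data.frame(query = "A1", subject = "B1", bitscore = 100))
  ba <- quick_hits(data.frame(query = "B1", subject = "A1", bitscore = 95),
                   "B", "A")
  r <- reciprocal_best_hits(ab, ba, "protein")
  expect_equal(r$gene_a, "A1")

  ba2 <- quick_hits(data.frame(query = "B1", subject = "A2", bitscore = 95),
                    "B", "A")
  expect_equal(nrow(reciprocal_best_hits(ab, ba2, "protein")), 0L)

  # ratio 100/210 = 0.476: dropped from the filtered channel only
  la <- c(A1 = 100); lb <- c(B1 = 210)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, "protein_filtered",
                                         la, lb)), 0L)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, "protein", la, lb)), 1L)

  # exact boundaries 0.5 and 2.0 are retained (closed interval)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, "protein_filtered",
                                         c(A1 = 100), c(B1 = 200))), 1L)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, "protein_filtered",
                                         c(A1 = 200), c(B1 = 100))), 1L)
  expect_error(reciprocal_best_hits(ab, ba, "protein_filtered",
                                    c(A1 = 100), c(other = 1)),
               "missing sequence length")
})

test_that("reciprocal_best_hits matches the exhaustive oracle on random instances", {
  set.seed(42)
  for (rep in 1:60) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    ga <- paste0("A", 1:na); gb <- paste0("B", 1:nb)
    # sparse random score matrix
    sc_ab <- matrix(ifelse(runif(na * nb) < 0.7,
                           sample(20:200, na * nb, TRUE), NA),
                    na, nb, dimnames = list(ga, gb))
    sc_ba <- matrix(ifelse(runif(na * nb) < 0.7,
                           sample(20:200, na * nb, TRUE), NA),
                    nb, na, dimnames = list(gb, ga))
    ev_ab <- matrix(0, na, nb, dimnames = list(ga, gb))
    ev_ba <- matrix(0, nb, na, dimnames = list(gb, ga))
    len_a <- setNames(sample(50:200, na), ga)
    len_b <- setNames(sample(50:200, nb), gb)
    to_hits <- function(sc, ev, qg, sg) {
      ix <- which(!is.na(sc), arr.ind = TRUE)
      quick_hits(data.frame(query = rownames(sc)[ix[, 1]],
                            subject = colnames(sc)[ix[, 2]],
                            bitscore = sc[ix], evalue = ev[ix]), qg, sg)
    }
    hab <- to_hits(sc_ab, ev_ab, "A", "B")
    hba <- to_hits(sc_ba, ev_ba, "B", "A")
    got <- reciprocal_best_hits(hab, hba, "protein_filtered", len_a, len_b)
    want <- oracle_rbh(sc_ab, ev_ab, sc_ba, ev_ba, len_a, len_b,
                       ratio = c(0.5, 2))
    expect_setequal(paste(got$gene_a, got$gene_b),
                    vapply(want, paste, character(1), collapse = " "))
    # unfiltered channel against the oracle without ratio
    got2 <- reciprocal_best_hits(hab, hba, "protein")
    want2 <- oracle_rbh(sc_ab, ev_ab, sc_ba, ev_ba)
    expect_setequal(paste(got2$gene_a, got2$gene_b),
                    vapply(want2, paste, character(1), collapse = " "))
  }
})

test_that("anchor pool is the union of evidence channels", {
  rbh_f <- data.frame(gene_a = "R1", gene_b = "X1")
  rbh_p <- data.frame(gene_a = c("R1", "R2"), gene_b = c("X1", "X2"))
  rbh_c <- data.frame(gene_a = "R3", gene_b = "X3")
  syn <- data.frame(gene_a = "R1", gene_b = "X4")
  pool <- build_anchor_pool(rbh_f, rbh_p, rbh_c, syn)
  expect_setequal(pool$gene_id, c("X1", "X2", "X3", "X4"))
  expect_equal(pool$evidence[pool$gene_id == "X1"],
               "protein_filtered,protein")
  expect_equal(pool$evidence[pool$gene_id == "X3"], "cds")
  # absent gene stays absent
  expect_false("X9" %in% pool$gene_id)

  # cardinality equals the set-union oracle on random channel sets
  set.seed(9)
  for (i in 1:30) {
    univ <- paste0("g", 1:12)
    chans <- lapply(1:4, function(k) sample(univ, sample(0:8, 1)))
    dfs <- lapply(chans, function(g)
      data.frame(gene_a = g, gene_b = g, stringsAsFactors = FALSE))
    pool <- build_anchor_pool(dfs[[1]], dfs[[2]], dfs[[3]], dfs[[4]])
    expect_equal(nrow(pool), length(unique(unlist(chans))))
  }
})

test_that("expansion screen applies forward pool, top-2 reverse and self-hit removal", {
  fwd <- list(X = quick_hits(data.frame(
    query = c("anchor", "anchor"), subject = c("c1", "c2"),
    bitscore = c(100, 90)), "A", "X"))
  mk_rev <- function(df) list(X = quick_hits(df, "X", "A"))
  fam <- c("F1", "F2")

  # top-2 reverse subjects contain one family member -> in
  rev1 <- mk_rev(data.frame(query = "c1", subject = c("F1", "other"),
                            bitscore = c(100, 90)))
  expect_equal(expand_family("anchor", fwd, rev1, fam)$X, "c1")

  # both reverse subjects non-members -> out
  rev2 <- mk_rev(data.frame(query = "c1", subject = c("o1", "o2"),
                            bitscore = c(100, 90)))
  expect_equal(length(expand_family("anchor", fwd, rev2, fam)$X), 0L)

  # family member ranked third -> out (max two targets)
  rev3 <- mk_rev(data.frame(query = "c1", subject = c("o1", "o2", "F1"),
                            bitscore = c(100, 90, 80)))
  expect_equal(length(expand_family("anchor", fwd, rev3, fam)$X), 0L)

  # self-hit occupying a slot does not block the remaining subject
  rev4 <- mk_rev(data.frame(query = "c1", subject = c("c1", "F1"),
                            bitscore = c(500, 90)))
  expect_equal(expand_family("anchor", fwd, rev4, fam)$X, "c1")

  # reverse hits only to itself -> out
  rev5 <- mk_rev(data.frame(query = "c1", subject = "c1", bitscore = 500))
  expect_equal(length(expand_family("anchor", fwd, rev5, fam)$X), 0L)

  expect_error(expand_family("anchor", fwd, rev1, character(0)),
               "reference_family")

  # monotone in the reference family
  rev6 <- mk_rev(data.frame(query = c("c1", "c2"),
                            subject = c("F1", "Fx"),
                            bitscore = c(100, 100)))
  small <- expand_family("anchor", fwd, rev6, "F1")$X
  grown <- expand_family("anchor", fwd, rev6, c("F1", "Fx"))$X
  expect_true(all(small %in% grown))
})

test_that("seeded aligner reports full-identity self hits and no hit without a seed", {
  set.seed(5)
  p <- random_protein(50)
  h <- seeded_align(p, p, "a", "b")
  expect_equal(h$pct_identity, 100)
  expect_equal(h$aln_length, 50L)
  expect_equal(h$q_start, 1L)
  expect_equal(h$q_end, 50L)

  # sequences engineered to share no 5-mer
  p1 <- paste(rep("ACDEF", 8), collapse = "")
  p2 <- paste(rep("WYKRH", 8), collapse = "")
  expect_null(seeded_align(p1, p2))
  expect_error(seeded_align("", p), "empty")
})

test_that("seeded aligner score equals the exhaustive Smith-Waterman oracle", {
  mat <- famscape:::.blosum62()
  set.seed(31)
  for (i in 1:30) {
    s1 <- random_protein(sample(4:7, 1))
    # guarantee a shared single-residue seed so the comparison exercises
    # the alignment rather than the k-mer prescreen
    s2 <- paste0(random_protein(sample(3:6, 1)), substr(s1, 1, 1))
    want <- oracle_local_score(s1, s2, mat, 10, 1)
    got <- seeded_align(s1, s2, k = 1L, min_score = 1)
    expect_false(is.null(got))
    expect_equal(got$bitscore, want)
  }
})
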