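test_that("global protein alignment handles identity, single indels and empty input", {
  set.seed(2)
  p <- random_protein(10)
  a <- align_protein_pair(p, p)
  expect_equal(a$a1, p)
  expect_equal(a$a2, p)

  # one inserted residue -> exactly one single-column gap
  p2 <- paste0(substr(p, 1, 5), "W", substr(p, 6, 10))
  a2 <- align_protein_pair(p, p2)
  gaps <- gregexpr("-+", a2$a1)[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 1L)
  expect_false(grepl("-", a2$a2))

  expect_error(align_protein_pair("", p), "empty")
})

test_that("global alignment score equals the exhaustive oracle on short sequences", {
  mat <- famscape:::.blosum62()
  set.seed(19)
  for (i in 1:50) {
    s1 <- random_protein(sample(2:4, 1))
    s2 <- random_protein(sample(2:4, 1))
    expect_equal(align_protein_pair(s1, s2)$score,
                 oracle_global_score(s1, s2, mat, 10, 1))
  }
})

test_that("backtranslation maps residues to source codons and gaps to ---", {
  aln <- list(a1 = "MK-", a2 = "MKR")
  ca <- backtranslate(aln, "ATGAAA", "ATGAAACGT")
  expect_equal(ca$cds1, "ATGAAA---")
  expect_equal(ca$cds2, "ATGAAACGT")

  # terminal stop stripped before mapping
  ca2 <- backtranslate(aln, "ATGAAATGA", "ATGAAACGTTAA")
  expect_equal(ca2$cds1, "ATGAAA---")

  expect_error(backtranslate(list(a1 = "MK", a2 = "MR"),
                             "ATGAAA", "ATGAAA"),
               "residue position 2")
  expect_equal(nchar(backtranslate(list(a1 = "", a2 = ""), "", "")$cds1), 0L)

  # whole-codon gap validation in the constructor
  expect_error(codon_alignment("ATG-AA", "ATGAAA"), "whole-codon")
})

test_that("NG86 site counts match single-base mutant enumeration", {
  expect_equal(ng86_site_counts("ATG"), c(S = 0, N = 3))
  expect_equal(ng86_site_counts("GTT"), c(S = 1, N = 2))
  expect_equal(ng86_site_counts("TGG"), c(S = 0, N = 3))
  expect_error(ng86_site_counts("TAA"), "stop")
  expect_error(ng86_site_counts("ANG"), "codon")

  # against independent enumeration for every sense codon
  code <- Biostrings::GENETIC_CODE
  for (cd in names(code)[code != "*"]) {
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(c("A", "C", "G", "T"), substr(cd, p, p))
      aa <- vapply(alts, function(b) {
        m <- cd; substr(m, p, p) <- b; code[[m]]
      }, character(1))
      keep <- aa != "*"
      if (any(keep)) s <- s + sum(aa[keep] == code[[cd]]) / sum(keep)
    }
    expect_equal(unname(ng86_site_counts(cd)["S"]), s)
  }
})

test_that("pairwise Ka/Ks reproduces the hand-computed worked example", {
  r <- kaks_pairwise(codon_alignment("GTTGTT", "GTCGTT"))
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 0.5)
  expect_equal(r$Ks, -0.75 * log(1 / 3), tolerance = 1e-12)
  expect_equal(r$Ka, 0)

  ident <- kaks_pairwise(codon_alignment("ATGAAA", "ATGAAA"))
  expect_equal(ident$Sd, 0)
  expect_equal(ident$Ka, 0)
  expect_equal(ident$Ks, 0)
  expect_true(is.na(ident$omega))        # omega undefined at Ks = 0
})

test_that("Ka/Ks agrees with an independently coded NG86 oracle and is symmetric", {
  set.seed(33)
  cds1 <- random_sense_cds(300)
  cds2 <- evolve_cds(cds1, 0.4, 1.2, seed = 9)
  r <- kaks_pairwise(codon_alignment(cds1, cds2))
  o <- oracle_ng86(cds1, cds2)
  expect_equal(r$S, o$S, tolerance = 1e-9)
  expect_equal(r$N, o$N, tolerance = 1e-9)
  expect_equal(r$Sd, o$Sd, tolerance = 1e-9)
  expect_equal(r$Nd, o$Nd, tolerance = 1e-9)
  expect_equal(r$Ks, o$Ks, tolerance = 1e-9)
  expect_equal(r$Ka, o$Ka, tolerance = 1e-9)

  # symmetric in the two sequences
  r2 <- kaks_pairwise(codon_alignment(cds2, cds1))
  expect_equal(r$Ks, r2$Ks)
  expect_equal(r$Ka, r2$Ka)
  expect_equal(r$S, r2$S)

  # site conservation over compared codons
  expect_equal(r$S + r$N, 3 * r$n_codons)

  # JC limit: at low divergence Ks ~ ps and Ka ~ pn
  cds3 <- evolve_cds(cds1, 0.005, 1, seed = 4)
  r3 <- kaks_pairwise(codon_alignment(cds1, cds3))
  if (r3$ps > 0) expect_equal(r3$Ks / r3$ps, 1, tolerance = 0.01)
  if (r3$pn > 0) expect_equal(r3$Ka / r3$pn, 1, tolerance = 0.01)
})

test_that("gapped and ambiguous codon columns are excluded pairwise", {
  r <- kaks_pairwise(codon_alignment("ATG---GTT", "ATGAAAGTC"))
  expect_equal(r$n_codons, 2L)
  rn <- kaks_pairwise(codon_alignment("ATGNNNGTT", "ATGAAAGTC"))
  expect_equal(rn$n_codons, 2L)
  expect_error(kaks_pairwise(codon_alignment("---", "AAA")),
               "no comparable")
  expect_error(kaks_pairwise(codon_alignment("TAA", "AAA")), "stop codon")
})

test_that("class pairing follows the per-class selection rules", {
  arrays <- list(list(species_tag = "sp", seq_id = "c1",
                      members = c("g1", "g2", "g3", "g4")))
  labels <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "o1", "o2", "o3", "s1", "s2"),
    is_tandem = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_ohnolog = c(rep(FALSE, 4), TRUE, TRUE, TRUE, FALSE, FALSE),
    klass = c(rep("tandem", 4), rep("ohnolog", 3), rep("singleton", 2)),
    stringsAsFactors = FALSE)
  groups <- data.frame(group_id = 1L, gene_id = c("o1", "o2", "o3"),
                       size = 3L, flagged = FALSE)
  hits <- quick_hits(data.frame(
    query = c("o1", "o1", "o2", "o3", "s1", "s2"),
    subject = c("o2", "o3", "o1", "o1", "s2", "s1"),
    bitscore = c(300, 200, 300, 150, 80, 80)), "sp", "sp")
  pairs <- select_class_pairs(labels, arrays, groups, hits)

  # tandem: first with last member by coordinate
  tand <- pairs[pairs$class == "tandem", ]
  expect_equal(nrow(tand), 1L)
  expect_setequal(c(tand$gene_a, tand$gene_b), c("g1", "g4"))

  # ohnolog triplet contributes only its highest-scoring pair
  ohno <- pairs[pairs$class == "ohnolog", ]
  expect_equal(nrow(ohno), 1L)
  expect_setequal(c(ohno$gene_a, ohno$gene_b), c("o1", "o2"))

  # two mutually-best singletons collapse to one unordered pair
  sing <- pairs[pairs$class == "singleton", ]
  expect_equal(nrow(sing), 1L)

  # singleton without any within-species family hit is skipped
  labels2 <- rbind(labels, data.frame(gene_id = "lonely",
                                      is_tandem = FALSE,
                                      is_ohnolog = FALSE,
                                      klass = "singleton"))
  expect_warning(select_class_pairs(labels2, arrays, groups, hits),
                 "lonely")
})

test_that("class rate summaries average defined omegas only", {
  rates <- data.frame(class = c("a", "a", "b", "b"),
                      omega = c(1, 2, 1, NA))
  s <- summarize_class_rates(rates, test = TRUE)
  expect_equal(s$mean_omega[s$class == "a"], 1.5)
  expect_equal(s$mean_omega[s$class == "b"], 1)
  expect_equal(s$n_defined[s$class == "b"], 1L)
  expect_false(is.null(attr(s, "tests")))

  s2 <- summarize_class_rates(data.frame(class = "z", omega = NA_real_))
  expect_equal(s2$n_defined, 0L)
  expect_true(is.na(s2$mean_omega))
})

test_that("domain-restricted rates use only the requested residue ranges", {
  set.seed(44)
  cds <- random_sense_cds(60)
  # diverge only codons 31..60; region restricted to 1..30 sees no change
  out <- evolve_cds(cds, 0.4, 1, seed = 5, keep_aa = 1:30)
  ann <- genome_annotation(
    "sp",
    data.frame(gene_id = c("a", "b"), seq_id = "c1", start = c(1, 1000),
               end = c(180, 1180) - 1 + 1, strand = "+"),
    c(a = cds, b = out),
    c(a = translate_cds(cds), b = translate_cds(out)))
  r_front <- rates_for_pair(ann, "a", "b",
                            regions = data.frame(start = 1, end = 30))
  expect_equal(r_front$Ka, 0)             # amino acids protected there
  r_all <- rates_for_pair(ann, "a", "b")
  expect_gt(r_all$Nd, 0)
})
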