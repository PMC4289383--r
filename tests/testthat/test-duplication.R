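test_that("tandem pairs require same sequence, spacer window and a hit", {
  set.seed(8)
  ann <- tiny_genome("sp", rep("chr1", 30),
                     seq(100, by = 1000, length.out = 30))
  g <- ann$genes$gene_id[order(ann$genes$rank)]

  # ranks 10 and 21: exactly 10 spacers -> linked
  h <- quick_hits(data.frame(query = g[11], subject = g[22],
                             bitscore = 100), "sp", "sp")
  arr <- detect_tandem_arrays(c(g[11], g[22]), ann, h)
  expect_length(arr, 1L)
  expect_equal(arr[[1]]$members, c(g[11], g[22]))

  # ranks 10 and 22: 11 spacers -> no array
  h2 <- quick_hits(data.frame(query = g[11], subject = g[23],
                              bitscore = 100), "sp", "sp")
  expect_length(detect_tandem_arrays(c(g[11], g[23]), ann, h2), 0L)

  # transitivity: hits 0-5 and 5-10 only -> one array of all three
  h3 <- quick_hits(data.frame(query = c(g[1], g[6]),
                              subject = c(g[6], g[11]),
                              bitscore = c(100, 100)), "sp", "sp")
  arr3 <- detect_tandem_arrays(c(g[1], g[6], g[11]), ann, h3)
  expect_length(arr3, 1L)
  expect_equal(arr3[[1]]$members, c(g[1], g[6], g[11]))

  # strong hit across chromosomes is ignored (transpositional filter)
  ann2 <- tiny_genome("sp2", c("chr1", "chr2"), c(100, 100))
  g2 <- ann2$genes$gene_id
  h4 <- quick_hits(data.frame(query = g2[1], subject = g2[2],
                              bitscore = 5000), "sp2", "sp2")
  expect_length(detect_tandem_arrays(g2, ann2, h4), 0L)

  # arrays partition genes: no gene in two arrays
  h5 <- quick_hits(data.frame(query = c(g[1], g[6], g[25]),
                              subject = c(g[6], g[11], g[27]),
                              bitscore = 100), "sp", "sp")
  arr5 <- detect_tandem_arrays(c(g[1], g[6], g[11], g[25], g[27]), ann, h5)
  members <- unlist(lapply(arr5, `[[`, "members"))
  expect_equal(anyDuplicated(members), 0L)
})

test_that("duplicate classes follow the non-exclusive pool definitions", {
  arrays <- list(list(species_tag = "sp", seq_id = "c1",
                      members = c("t1", "t2")))
  groups <- data.frame(group_id = 1L, gene_id = c("o1", "t1"),
                       size = 2L, flagged = FALSE)
  lab <- classify_duplicates(c("t1", "t2", "o1", "s1"), arrays, groups)
  expect_equal(lab$klass[lab$gene_id == "t2"], "tandem")
  expect_equal(lab$klass[lab$gene_id == "o1"], "ohnolog")
  expect_equal(lab$klass[lab$gene_id == "s1"], "singleton")
  expect_equal(lab$klass[lab$gene_id == "t1"], "tandem+ohnolog")
  # singleton iff neither flag
  expect_equal(lab$klass == "singleton", !lab$is_tandem & !lab$is_ohnolog)
})

test_that("array summaries compute fractions, means and a totals row", {
  arrays <- list(sp = list(
    list(species_tag = "sp", seq_id = "c1", members = c("a", "b"))))
  t1 <- summarize_arrays(arrays, c(sp = 4))
  expect_equal(t1$pct_tandem[1], 50)
  expect_equal(t1$mean_genes_per_array[1], 2.0)
  expect_equal(t1$largest_array[1], 2)

  none <- summarize_arrays(list(sp = list()), c(sp = 5))
  expect_equal(none$pct_tandem[1], 0)
  expect_equal(none$n_arrays[1], 0L)

  # totals row sums counts and recomputes global ratios
  arrays2 <- list(
    s1 = list(list(species_tag = "s1", seq_id = "c", members = letters[1:3]),
              list(species_tag = "s1", seq_id = "c", members = letters[4:5])),
    s2 = list(list(species_tag = "s2", seq_id = "c", members = letters[6:7])))
  t2 <- summarize_arrays(arrays2, c(s1 = 10, s2 = 4))
  sig <- t2[t2$species == "Sigma", ]
  expect_equal(sig$family_size, 14)
  expect_equal(sig$n_tandem, 7)
  expect_equal(sig$pct_tandem, 50)
  expect_equal(sig$n_arrays, 3)
  expect_equal(sig$mean_genes_per_array, round(7 / 3, 1))
  expect_equal(sig$largest_array, (3 + 2) / 2)
  # tandem duplicate total equals the sum of array sizes
  expect_equal(sig$n_tandem,
               sum(attr(t2, "size_histogram")$array_size *
                     attr(t2, "size_histogram")$n_arrays))
  expect_equal(attr(t2, "frac_size2"), 2 / 3)
})

test_that("tandem fraction is monotone in the spacer window", {
  set.seed(14)
  ann <- tiny_genome("sp", rep("chr1", 40),
                     seq(100, by = 1000, length.out = 40))
  g <- ann$genes$gene_id[order(ann$genes$rank)]
  fam <- g[c(1, 4, 9, 16, 25, 36)]
  h <- quick_hits(data.frame(query = fam[-length(fam)],
                             subject = fam[-1],
                             bitscore = 100), "sp", "sp")
  frac <- vapply(c(1L, 3L, 7L, 12L, 40L), function(w) {
    arr <- detect_tandem_arrays(fam, ann, h, window = w)
    sum(lengths(lapply(arr, `[[`, "members"))) / length(fam)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
})

test_that("ohnolog summaries report percentages and enrichment", {
  t2 <- summarize_ohnologs(list(
    all_in = list(n_ohno_genome = 10, n_genes = 10,
                  n_ohno_family = 4, n_family = 4)))
  expect_equal(t2$pct_genomewide[1], 100)
  expect_equal(t2$pct_family[1], 100)
  expect_false(t2$enriched[1])

  df <- data.frame(species = "tuber", pct_genomewide = 10, pct_family = 5)
  expect_false(summarize_ohnologs(df)$enriched[1])
})
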