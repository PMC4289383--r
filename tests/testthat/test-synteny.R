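mk_pairs <- function(rx, ry) {
  data.frame(gene_x = paste0("x", seq_along(rx)),
             gene_y = paste0("y", seq_along(ry)),
             rank_x = rx, rank_y = ry, stringsAsFactors = FALSE)
}

test_that("collinear chaining respects min size, gap and orientation", {
  # perfect diagonal of 5
  b <- chain_collinear_pairs(mk_pairs(1:5, 11:15))
  expect_length(b, 1L)
  expect_equal(b[[1]]$n_pairs, 5L)
  expect_equal(b[[1]]$orientation, "same")
  expect_true(all(diff(b[[1]]$pairs$rank_x) > 0))
  expect_true(all(diff(b[[1]]$pairs$rank_y) > 0))

  # 4 pairs: below the minimum cluster size
  expect_length(chain_collinear_pairs(mk_pairs(1:4, 1:4)), 0L)

  # an internal gap of 21 ranks splits the chain into sub-threshold pieces
  rx <- c(1, 2, 3, 25, 26)
  expect_length(chain_collinear_pairs(mk_pairs(rx, rx)), 0L)
  # while a gap of exactly 20 still chains
  rx20 <- c(1, 2, 3, 23, 24)
  expect_length(chain_collinear_pairs(mk_pairs(rx20, rx20)), 1L)

  # inverted diagonal
  binv <- chain_collinear_pairs(mk_pairs(1:5, 15:11))
  expect_equal(binv[[1]]$orientation, "inverted")
})

test_that("chaining matches the exhaustive enumeration oracle", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(6:10, 1)
    px <- sample(1:30, n)
    py <- sample(1:30, n)
    pairs <- mk_pairs(px, py)
    got <- chain_collinear_pairs(pairs, max_gap = 8L, min_size = 3L)
    want <- oracle_chain_blocks(pairs, max_gap = 8L, min_size = 3L)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$pairs[c("rank_x", "rank_y")],
                   want[[k]]$pairs[c("rank_x", "rank_y")],
                   ignore_attr = TRUE)
      expect_equal(got[[k]]$orientation, want[[k]]$orientation)
    }
    # every emitted block is strictly monotone on both axes
    for (blk in got) {
      expect_true(all(diff(blk$pairs$rank_x) > 0))
      dy <- diff(blk$pairs$rank_y)
      expect_true(all(dy > 0) || all(dy < 0))
    }
  }
})

test_that("block merging applies the spacer threshold transitively", {
  mk_block <- function(rx, ry, ks = NA_real_) {
    p <- mk_pairs(rx, ry)
    p$ks <- ks
    list(pairs = p, orientation = "same", seq_x = "c1", seq_y = "c1",
         n_pairs = nrow(p), mean_ks = NA_real_)
  }
  b1 <- mk_block(1:5, 1:5, 0.2)
  b2 <- mk_block(306:310, 306:310, 0.4)      # 300 ranks away
  m <- merge_blocks(list(b1, b2))
  expect_length(m, 1L)
  expect_equal(m[[1]]$n_pairs, 10L)
  expect_equal(m[[1]]$mean_ks, 0.3)

  b3 <- mk_block(357:361, 357:361)           # 351 ranks away from b1
  expect_length(merge_blocks(list(b1, b3)), 2L)
  # exactly 350 merges
  b350 <- mk_block(356:360, 356:360)
  expect_length(merge_blocks(list(b1, b350)), 1L)

  # opposite orientations never merge
  b2i <- mk_block(306:310, 310:306)
  b2i$orientation <- "inverted"
  expect_length(merge_blocks(list(b1, b2i)), 2L)

  # transitive: a-b gap 300, b-c gap 300, a-c gap 605
  bc <- mk_block(611:615, 611:615)
  expect_length(merge_blocks(list(b1, b2, bc)), 1L)
})

test_that("Ks filtering retains blocks inside the mean-Ks window", {
  mk_block <- function(ks) {
    p <- mk_pairs(1:5, 1:5)
    p$ks <- ks
    list(pairs = p, orientation = "same", seq_x = "c1", seq_y = "c2",
         n_pairs = 5L, mean_ks = NA_real_)
  }
  expect_length(ks_filter_blocks(list(mk_block(1.6))), 0L)
  expect_length(ks_filter_blocks(list(mk_block(1.5))), 1L)   # boundary kept
  kept <- ks_filter_blocks(list(mk_block(0.8)))
  expect_equal(kept[[1]]$mean_ks, 0.8)
  expect_length(ks_filter_blocks(list(mk_block(0))), 1L)     # identical dup

  # rate_fn failures: pairs skipped with warning; all-failed block dropped
  b <- mk_block(NA_real_)
  b$pairs$ks <- NULL
  warns <- capture_warnings(
    out <- ks_filter_blocks(list(b), function(x, y) stop("no")))
  expect_true(any(grepl("skipped", warns)))
  expect_true(any(grepl("no computable", warns)))
  expect_length(out, 0L)
})

test_that("greedy depth screening enforces per-rank quotas", {
  mk_block <- function(rx, ry, sx = "c1", sy = "c2") {
    p <- mk_pairs(rx, ry)
    list(pairs = p, orientation = "same", seq_x = sx, seq_y = sy,
         n_pairs = nrow(p), mean_ks = 0.5)
  }
  big <- mk_block(1:9, 1:9)
  small <- mk_block(3:7, 11:15)              # overlaps big on genome X
  kept <- screen_depth(list(big, small), 1L, 1L)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$n_pairs, 9L)

  # quota 1:2 with overlap only on genome Y keeps both
  b1 <- mk_block(1:5, 1:5)
  b2 <- mk_block(11:15, 3:7)                 # overlaps b1 only on Y
  expect_length(screen_depth(list(b1, b2), 1L, 2L), 2L)
  expect_length(screen_depth(list(b1, b2), 1L, 1L), 1L)

  # disjoint blocks are all kept regardless of quota
  b3 <- mk_block(21:25, 21:25)
  expect_length(screen_depth(list(b1, b3), 1L, 1L), 2L)
})

test_that("ohnolog groups are connected components of retained anchors", {
  mk_block <- function(gx, gy) {
    p <- data.frame(gene_x = gx, gene_y = gy,
                    rank_x = seq_along(gx), rank_y = seq_along(gy),
                    stringsAsFactors = FALSE)
    list(pairs = p, orientation = "same", seq_x = "c1", seq_y = "c2",
         n_pairs = nrow(p), mean_ks = 0.5)
  }
  fam <- c("f1", "f2", "f3", "f4")
  g <- assign_ohnolog_groups(list(mk_block(c("f1", "b1"), c("f2", "b2"))),
                             fam)
  expect_equal(nrow(g), 2L)
  expect_equal(unique(g$size), 2L)

  # one gene anchored to two partners -> triplet
  g3 <- assign_ohnolog_groups(list(mk_block("f1", "f2"),
                                   mk_block("f1", "f3")), fam)
  expect_equal(sort(unique(g3$size)), 3L)
  expect_false(any(g3$flagged))

  # gene in no retained block -> no group
  expect_false("f4" %in% g3$gene_id)
  expect_equal(nrow(assign_ohnolog_groups(list(), fam)), 0L)
})

test_that("self-comparison of an unduplicated genome yields no blocks", {
  set.seed(21)
  ann <- tiny_genome("solo", rep("chr1", 30),
                     seq(100, by = 1000, length.out = 30), codons = 40L)
  hits <- align_genomes(ann, ann)
  pairs <- anchor_pairs_from_hits(hits, ann, ann, self = TRUE)
  blocks <- chain_all_sequences(pairs)
  expect_length(blocks, 0L)
})
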