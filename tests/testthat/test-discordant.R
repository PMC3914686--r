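test_that("pair classification follows orientation, insert and mapq rules", {
  p <- pair_table(
    pair_row(left_start = 100L, left_end = 175L, right_start = 325L,
             right_end = 400L),                              # insert 300
    pair_row(left_start = 100L, left_end = 175L, right_start = 1525L,
             right_end = 1600L, mapq_left = 37L, mapq_right = 37L),
    pair_row(left_start = 100L, left_end = 175L, right_start = 325L,
             right_end = 400L, strand_right = "+"),          # (+,+)
    pair_row(left_start = 100L, left_end = 175L, right_start = 1525L,
             right_end = 1600L, mapq_left = 20L))
  cls <- classify_pairs(p)
  expect_equal(cls$class,
               c("normal", "discordant", "discordant", "low_quality"))
  expect_equal(cls$signature[2], "deletion_signal")
  expect_equal(cls$signature[3], "inversion_signal")
  ## boundary: mapq 29 is usable, insert 1000 is discordant
  b <- classify_pairs(pair_table(
    pair_row(left_start = 0L, left_end = 75L, right_start = 925L,
             right_end = 1000L, mapq_left = 29L)))
  expect_equal(b$class, "discordant")
  expect_equal(b$insert_span, 1000L)
  ## eversion and interchromosomal signatures map later to transposition
  ev <- classify_pairs(pair_table(
    pair_row(strand_left = "-", strand_right = "+")))
  expect_equal(ev$signature, "eversion_signal")
  ic <- pair_row()
  ic$chrom_right <- "chr2"
  expect_equal(classify_pairs(ic)$signature, "interchrom_signal")
})

test_that("pooling keeps accession labels and counts contributions", {
  mk <- function(acc, n) {
    do.call(pair_table, lapply(seq_len(n), function(i) {
      pair_row(accession = acc, left_start = 100L * i, left_end = 100L * i + 75L,
               right_start = 100L * i + 1500L, right_end = 100L * i + 1575L,
               id = paste0(acc, ":", i))
    }))
  }
  cls <- lapply(list(mk("a", 5), mk("b", 0), mk("c", 2)), classify_pairs)
  pool <- pool_discordant(cls)
  expect_equal(nrow(pool), 7L)
  expect_equal(as.integer(attr(pool, "counts")[c("a", "c")]), c(5L, 2L))
  expect_equal(nrow(pool_discordant(list())), 0L)
  ## same local ids in different accessions stay distinct
  dup <- pool_discordant(lapply(list(mk("a", 2), mk("b", 2)),
                                classify_pairs))
  expect_equal(length(unique(dup$pair_id)), 4L)
})

test_that("two-dimensional clustering respects window and support rules", {
  pool <- pool_discordant(classify_pairs(
    del_pairs(c(100L, 150L, 200L), c(5100L, 5150L, 5200L))))
  cl <- cluster_pairs(pool)
  expect_equal(length(unique(cl$cluster_id)), 1L)
  expect_equal(nrow(cl), 3L)

  two <- pool_discordant(classify_pairs(
    del_pairs(c(100L, 150L), c(5100L, 5150L))))
  expect_equal(nrow(cluster_pairs(two)), 0L)

  split_r <- pool_discordant(classify_pairs(
    del_pairs(c(100L, 150L, 200L), c(5100L, 15150L, 25200L))))
  expect_equal(nrow(cluster_pairs(split_r)), 0L)

  expect_error(cluster_pairs(pool, window = 0), "window")
  expect_error(cluster_pairs(pool, min_support = 0), "min_support")
})

test_that("clustering partitions pairs independently of input order", {
  set.seed(42)
  lefts <- as.integer(sample(0:50000, 300, TRUE))
  rights <- lefts + as.integer(sample(1200:30000, 300, TRUE))
  pool <- pool_discordant(classify_pairs(del_pairs(lefts, rights)))
  memb <- function(pool) {
    cl <- cluster_pairs(pool, min_support = 1)
    split(cl$pair_id, cl$cluster_id) |>
      lapply(sort) |> unname() |> (\(x) x[order(sapply(x, `[`, 1))])()
  }
  m1 <- memb(pool)
  m2 <- memb(pool[sample(nrow(pool)), ])
  expect_identical(m1, m2)
  ## a partition: every pair in at most one cluster
  cl <- cluster_pairs(pool, min_support = 1)
  expect_equal(anyDuplicated(cl$pair_id), 0L)
})

test_that("candidate intervals use inner anchor edges and reject crossed edges", {
  pool <- pool_discordant(classify_pairs(
    del_pairs(c(850L, 900L, 925L), c(5000L, 5050L, 5100L))))
  cand <- make_candidates(cluster_pairs(pool))
  expect_equal(cand$start, 1000L)   # max left_end = 925 + 75
  expect_equal(cand$end, 5000L)     # min right_start
  expect_equal(cand$size, 4000L)
  expect_equal(cand$sv_type, "deletion")
  expect_equal(cand$support, 3L)

  ## crossed inner edges -> non-positive size -> rejected
  crossed <- pool_discordant(classify_pairs(
    del_pairs(c(4925L, 4950L, 4975L), c(4000L, 4025L, 4050L))))
  crossed$left_start <- c(4925L, 4950L, 4975L)
  crossed$left_end <- crossed$left_start + 75L
  crossed$right_start <- c(4000L, 4025L, 4050L)
  crossed$insert_span <- 2000L   # force discordant deletion signature
  crossed$signature <- "deletion_signal"
  expect_equal(nrow(make_candidates(cluster_pairs(crossed))), 0L)

  inv <- classify_pairs(pair_table(
    pair_row(left_start = 100L, right_start = 300L, strand_right = "+",
             id = "a:1"),
    pair_row(left_start = 120L, right_start = 320L, strand_right = "+",
             id = "a:2"),
    pair_row(left_start = 140L, right_start = 340L, strand_right = "+",
             id = "a:3")))
  cand_inv <- make_candidates(cluster_pairs(pool_discordant(inv)))
  expect_equal(cand_inv$sv_type, "inversion")
})

test_that("a planted deletion with spanning pairs yields one localized candidate", {
  cfg <- noise_free_config(seed = 9)
  truth <- generate_truth(cfg)
  sim <- simulate_read_pairs(truth, cfg)
  svs <- call_svs(sim$pairs)
  dels <- svs$candidates[svs$candidates$sv_type == "deletion", ]
  tol <- cfg$insert_mean + 2 * cfg$insert_sd
  ## every planted deletion is recovered exactly once, breakpoints inside
  ## the anchor tolerance
  expect_equal(nrow(dels), nrow(truth$deletions))
  ord <- order(dels$start)
  expect_true(all(abs(dels$start[ord] - truth$deletions$start) <= tol))
  expect_true(all(abs(dels$end[ord] - truth$deletions$end) <= tol))
  ## and every retained cluster member is mapq-qualified and discordant
  expect_true(all(svs$pool$mapq_left >= 29 & svs$pool$mapq_right >= 29))
})
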