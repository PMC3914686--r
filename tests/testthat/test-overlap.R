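toy_features <- function() {
  data.frame(
    chrom = "chr1",
    start = c(1500L, 10000L, 20000L),
    end = c(3000L, 12000L, 22000L),
    kind = c("gene", "TE", "TE"),
    family = c(NA, "MULE", "Gypsy"),
    transcript_id = NA, gene_id = c("g1", NA, NA),
    strand = "+", longest = NA, stringsAsFactors = FALSE)
}

test_that("context assignment flags overlaps and builds the bp composition", {
  feats <- toy_features()
  mask <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  indels <- data.frame(id = c("a", "b"), start = c(100L, 10500L),
                       end = c(2100L, 11000L))
  res <- assign_context(indels, feats, mask)
  expect_true(res$assignments$genic[1])
  expect_false(res$assignments$te[1])
  expect_equal(res$assignments$gene_bp[1], 600L)  # [1500, 2100)
  expect_true(res$assignments$te[2])
  expect_error(assign_context(indels, feats, mask[0, ]), "mask")
})

test_that("uniformly planted indels match the alignable null; TE-only planting does not", {
  set.seed(23)
  cfg <- small_sim_config(seed = 23)
  truth <- generate_truth(cfg)
  G <- truth$genome_length
  ## null: 1 kb indels placed uniformly on the genome
  pos <- floor(runif(400, 0, G - 1000))
  unif <- data.frame(id = paste0("u", 1:400), start = as.integer(pos),
                     end = as.integer(pos + 1000))
  res <- assign_context(unif, truth$features, truth$mask)
  comp <- res$composition
  ## observed bp shares track the alignable-null expectation (the chisq
  ## p-value is not asserted under the null: bases within one indel are
  ## correlated, which overdisperses the bp-level statistic)
  expect_lt(abs(comp$indel_share[1] - comp$expected_share[1]), 0.05)
  expect_lt(abs(comp$indel_share[2] - comp$expected_share[2]), 0.05)
  ## indels planted only inside TEs
  tes <- truth$features[truth$features$kind == "TE" &
                          truth$features$end - truth$features$start > 600, ]
  te_ind <- data.frame(id = paste0("t", seq_len(nrow(tes))),
                       start = tes$start + 10L, end = tes$start + 510L)
  res2 <- assign_context(te_ind, truth$features, truth$mask)
  expect_equal(res2$composition$indel_share[2], 1.0)
  expect_lt(res2$chisq$p.value, 1e-10)
  ## bp attribution never exceeds the indel's length
  a <- res2$assignments
  expect_true(all(a$gene_bp + a$te_bp <= 2 * a$length))
  expect_true(all(a$te_bp == a$length))
})

test_that("transcript profiles are positional, strand-aware, and bounded", {
  ## plus-strand gene body 10 kb: exon/intron blocks
  feats <- data.frame(
    chrom = "chr1",
    start = c(0L, 4000L, 6000L),
    end = c(4000L, 6000L, 10000L),
    kind = c("exon", "intron", "exon"),
    family = NA, transcript_id = "tx", gene_id = "g",
    strand = "+", longest = TRUE, stringsAsFactors = FALSE)
  indel <- data.frame(id = "i", start = 0L, end = 1000L)  # first 10%
  pr <- transcript_profile(indel, feats)
  gb <- pr$gene_body
  expect_equal(sum(gb$counts[1:10]), 1000)
  expect_equal(sum(gb$counts[11:100]), 0)
  expect_equal(sum(gb$density), 1)
  ## reversing the strand reverses the bin vector exactly
  feats_m <- feats; feats_m$strand <- "-"
  pr_m <- transcript_profile(indel, feats_m)
  expect_equal(pr_m$gene_body$counts, rev(gb$counts))
  ## binomial 95% bounds at n = 10,000, p = 0.01
  feats2 <- feats; feats2$end[3] <- 10000L
  indel2 <- data.frame(id = "j", start = 0L, end = 10000L)
  pr2 <- transcript_profile(indel2, feats)
  expect_equal(pr2$gene_body$n, 10000)
  expect_equal(pr2$gene_body$lower, qbinom(0.025, 10000, 0.01))
  expect_equal(pr2$gene_body$upper, qbinom(0.975, 10000, 0.01))
  expect_equal(c(pr2$gene_body$lower, pr2$gene_body$upper), c(81, 120))
  ## no genic indels -> empty profile
  pr3 <- transcript_profile(data.frame(id = "k", start = 90000L,
                                       end = 91000L), feats)
  expect_equal(pr3$gene_body$n, 0)
})

test_that("TE-family purity assignment and Fisher enrichment", {
  feats <- toy_features()
  indels <- data.frame(id = c("x", "y"),
                       start = c(10000L, 20000L),
                       end = c(12000L, 22000L))
  ## x: 1900/2000 bp of MULE = 0.95 -> assigned
  feats$end[2] <- 11900L
  asn <- te_family_assign(indels, feats)
  expect_equal(asn$family[1], "MULE")
  expect_equal(asn$fraction[1], 0.95)
  ## 1700/2000 = 0.85 -> unassigned
  feats$end[2] <- 11700L
  asn2 <- te_family_assign(indels, feats)
  expect_true(is.na(asn2$family[1]))
  expect_error(te_family_assign(indels, feats, purity = 0), "purity")

  ## Fisher oracle by hypergeometric enumeration: the extreme 2x2 table
  ## [[10, 0], [0, 10]] has two-sided p = 2 / choose(20, 10)
  expect_equal(fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               2 / choose(20, 10), tolerance = 1e-10)
  feats3 <- data.frame(
    chrom = "chr1", start = seq(0, 19000, 1000), end = seq(500, 19500, 1000),
    kind = "TE", family = rep(c("MULE", "Gypsy"), each = 10),
    transcript_id = NA, gene_id = NA, strand = "+", longest = NA,
    stringsAsFactors = FALSE)
  asn3 <- data.frame(id = paste0("i", 1:10), family = "MULE",
                     fraction = 1)
  enr <- te_family_enrichment(asn3, feats3)
  mule <- enr[enr$family == "MULE", ]
  expect_equal(mule$observed, 10)
  expect_equal(mule$expected, 5)
  expect_equal(mule$fold, 2)
  ## independent evaluation of the documented 2x2 (sample vs annotation)
  expect_equal(mule$p,
               fisher.test(matrix(c(10, 0, 10, 10), 2))$p.value,
               tolerance = 1e-10)
  expect_equal(mule$p_bonferroni, min(1, mule$p * 2))
})

test_that("gene-family cluster-size comparison and enrichment", {
  fams <- data.frame(gene_id = paste0("g", 1:60),
                     family = rep(c("big", paste0("s", 1:30)),
                                  c(30, rep(1, 30))))
  ## indel genes drawn only from the largest family
  res <- gene_family_enrichment(paste0("g", 1:12), fams)
  expect_equal(res$median_indel, 30)
  expect_lt(res$utest$p.value, 0.01)
  big <- res$families[res$families$family == "big", ]
  expect_lt(big$p_bonferroni, 0.05)
  expect_gt(big$observed, big$expected)
  ## exact rank oracle: {1,2,3} vs {4,5,6} gives U = 0, two-sided p = 0.1
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 0.1)
})

test_that("window density correlation is exact under proportionality and scale-free", {
  set.seed(5)
  snp_pos <- runif(5000, 0, 5e6)
  indel_pos <- sample(snp_pos, 1000)   # indel tally proportional-ish
  ## strict proportionality: duplicate the snp positions
  r1 <- window_density_correlation(rep(snp_pos, 2), snp_pos, 1, 5e6)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  ## doubling coverage leaves normalized densities and r unchanged
  ra <- window_density_correlation(indel_pos, snp_pos, 10, 5e6)
  rb <- window_density_correlation(indel_pos, snp_pos, 20, 5e6)
  expect_equal(ra$r, rb$r)
  expect_error(window_density_correlation(1:10, 1:10, 1, 5e5, window = 5e5),
               "windows")
  ## independent tallies correlate near zero on average
  set.seed(6)
  rs <- replicate(30, window_density_correlation(
    runif(500, 0, 5e6), runif(5000, 0, 5e6), 1, 5e6)$r)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("size-by-MAF class means and Welch ANOVA behave", {
  set.seed(9)
  sizes <- c(rnorm(50, 5000, 400), rnorm(50, 5000, 400))
  maf <- rep(c(0.1, 0.2), each = 50)
  null <- size_by_maf(sizes, maf)
  expect_gt(null$anova$p.value, 1e-3)
  ## one class shifted by 10 kb is strongly significant
  shifted <- size_by_maf(c(sizes[1:50] + 10000, sizes[51:100]), maf)
  expect_lt(shifted$anova$p.value, 1e-10)
  expect_equal(unname(shifted$means["0.1"] - shifted$means["0.2"]), 10000,
               tolerance = 0.05)
  ## with exactly equal sample variances Welch's F equals the classical F
  a <- c(1, 2, 3, 4)
  b <- c(11, 12, 13, 14)
  w <- oneway.test(c(a, b) ~ rep(1:2, each = 4), var.equal = FALSE)
  cl <- oneway.test(c(a, b) ~ rep(1:2, each = 4), var.equal = TRUE)
  expect_equal(unname(w$statistic), unname(cl$statistic), tolerance = 1e-12)
})
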