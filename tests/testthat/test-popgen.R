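count_matrix <- function(n, counts) {
  ## sites as columns with given derived counts
  sapply(counts, function(k) c(rep(1L, k), rep(0L, n - k)))
}

test_that("SFS and MAF summaries fold correctly", {
  m <- count_matrix(10, c(1, 5, 9))
  s <- sfs_and_maf(m, polarized = TRUE)
  expect_equal(s$maf, c(0.1, 0.5, 0.1))
  expect_equal(s$mean_maf, mean(c(0.1, 0.5, 0.1)))
  expect_equal(s$unfolded, c(1, 0, 0, 0, 1, 0, 0, 0, 1))
  ## folding identity: eta_i = xi_i + xi_(n-i), eta_(n/2) = xi_(n/2)
  expect_equal(s$folded, c(2, 0, 0, 0, 1))
  expect_warning(sfs_and_maf(count_matrix(10, c(0, 3))), "monomorphic")
})

test_that("Tajima's D reproduces hand-evaluated and boundary cases", {
  ## pi = S/a1 makes the numerator exactly zero
  n <- 10; a1 <- sum(1 / (1:9))
  expect_equal(tajimas_d(round(a1 * 6), round(a1 * 6) / a1, n), 0)
  ## n = 4, derived counts (1, 2): hand-computed value
  expect_equal(tajimas_d(2, 7 / 6, 4), 0.592, tolerance = 1e-3)
  ## all-singleton data are skewed negative
  m <- count_matrix(10, rep(1, 30))
  expect_lt(tajimas_d(30, pairwise_pi(colSums(m), 10), 10), 0)
  expect_true(is.na(tajimas_d(0, 0, 10)))
})

test_that("Tajima's D equals a brute-force implementation on random matrices", {
  set.seed(13)
  for (r in 1:1000) {
    n <- sample(4:8, 1)
    S <- sample(1:12, 1)
    m <- count_matrix(n, sample(1:(n - 1), S, TRUE))
    ## scramble rows per column to decouple from the construction
    m <- apply(m, 2, sample)
    d1 <- tajimas_d(S, pairwise_pi(colSums(m), n), n)
    expect_equal(d1, brute_tajima(m), tolerance = 1e-12)
  }
})

test_that("normalized H reproduces identities, the hand case, and skew direction", {
  ## pi = theta_L: xi concentrated at the symmetric class
  expect_equal(fay_wu_h_norm(c(0, 3, 0), 4), 0)
  expect_equal(fay_wu_h_norm(c(2, 1, 0), 4), 0.709, tolerance = 1e-3)
  ## weight at the high-frequency-derived class drives H negative
  expect_lt(fay_wu_h_norm(c(0, 0, 5), 4), 0)
  expect_true(is.na(fay_wu_h_norm(rep(0, 9), 10)))
  expect_error(fay_wu_h_norm(c(1, 1), 4), "length")
  ## anti-monotone in mass moved from low to high frequency at fixed S
  xs <- sapply(0:5, function(k) fay_wu_h_norm(c(5 - k, 0, 0, 0, 0, 0, 0, 0,
                                                k), 10))
  expect_true(all(diff(xs) < 0))
})

test_that("outgroup polarization uses strict consensus", {
  focal <- cbind(c(rep("A", 7), rep("G", 3)),
                 c(rep("A", 7), rep("G", 3)),
                 c(rep("C", 5), rep("T", 5)))
  og <- rbind(c("A", "A", "C"),
              c("A", "G", "C"))
  p <- polarize(focal, og)
  expect_equal(p$ancestral[1], "A")
  expect_true(p$derived_minor[1])        # minor G is derived
  expect_true(is.na(p$ancestral[2]))     # outgroups disagree
  expect_equal(p$ancestral[3], "C")
  expect_false(is.na(p$derived_minor[3]))
})

test_that("polarization recovers the planted ancestral state exactly", {
  cfg <- small_sim_config(seed = 91)
  truth <- generate_truth(cfg)
  snps <- truth$snps
  carr <- carrier_matrix(truth, "snps")
  focal <- sapply(seq_len(nrow(snps)), function(j) {
    ifelse(carr[, j], snps$alt[j], snps$ref[j])
  })
  og <- rbind(ifelse(snps$derived, snps$ref, snps$alt),
              ifelse(snps$derived, snps$ref, snps$alt))
  p <- polarize(focal, og)
  truth_anc <- ifelse(snps$derived, snps$ref, snps$alt)
  expect_equal(p$ancestral, truth_anc)
  ## at MAF 0.5 the minor allele is an arbitrary pick; compare below it
  unambig <- snps$m < 5
  expect_equal(p$derived_minor[unambig], snps$derived[unambig])
})

test_that("delete-one jackknife matches the analytic SE of a mean", {
  const <- jackknife_ci(1:10, function(x) 5)
  expect_equal(const$se, 0)
  expect_equal(const$lower, const$upper)
  jm <- jackknife_ci(1:10, mean)
  expect_equal(jm$mean, mean(1:10))
  expect_equal(jm$se, sd(1:10) / sqrt(10), tolerance = 1e-12)
  expect_error(jackknife_ci(1:2, mean), "at least 3")
  expect_warning(
    jackknife_ci(1:5, function(x) if (length(x) == 4 && x[1] == 2) NA_real_
                 else mean(x)),
    "NA")
})

test_that("intra-allelic diversity counts carrier pairwise differences per bp", {
  ## 3 carriers with pairwise differences 1, 2, 3 over 500 bp
  h <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 1))
  expect_equal(pi_a(h), mean(c(1, 2, 3)) / 500)
  expect_equal(pi_a(matrix(0L, 3, 4)), 0)
  expect_true(is.na(pi_a(matrix(0L, 1, 4))))  # singleton carrier
  ## windowed per-locus version skips singletons and respects the window
  geno <- list(pos = c(100L, 300L, 900L),
               mat = matrix(c(0, 1, 1, 0, 0, 1, 0, 0, 0), 3,
                            dimnames = list(c("a", "b", "c"), NULL)))
  v <- pi_a_for_loci(c(250, 250), list(c("b", "c"), "a"), geno)
  expect_equal(v[1], 1 / 500)   # sites 100 and 300 in window; one diff
  expect_true(is.na(v[2]))
})

test_that("allele ages and the validation rate reproduce printed arithmetic", {
  expect_equal(round(allele_age(0.0031, 0.0087), 2), 0.36)
  expect_equal(round(allele_age(0.0047, 0.0087), 2), 0.54)
  expect_equal(round(allele_age(0.0055, 0.0087), 2), 0.63)
  expect_equal(allele_age(0.0087, 0.0087), 1.0)
  expect_error(allele_age(0.003, 0), "grand mean")
  expect_equal(round(validation_rate(24, 33), 1), 72.7)
})

test_that("the diffusion mean age matches the neutral closed form and is symmetric", {
  for (x in c(0.05, 0.2, 0.5, 0.8)) {
    expect_equal(mean_allele_age(x, 0), -2 * x * log(x) / (1 - x),
                 tolerance = 1e-9)
    ## the integrator at vanishing selection approaches the closed form
    expect_equal(mean_allele_age(x, 1e-4), -2 * x * log(x) / (1 - x),
                 tolerance = 1e-3)
  }
  for (g in c(0.5, 2, 5)) {
    expect_equal(mean_allele_age(0.2, g), mean_allele_age(0.2, -g),
                 tolerance = 1e-9)
  }
  ## strictly decreasing in |gamma|
  ages <- sapply(c(0, 0.5, 1, 2, 5, 10, 20), mean_allele_age, x = 0.2)
  expect_true(all(diff(ages) < 0))
})

test_that("selection-strength inversion recovers gamma on a grid", {
  for (g in c(0.3, 1, 2.5, 6, 12)) {
    Tg <- mean_allele_age(0.2, g)
    expect_equal(nes_from_age(Tg, 0.2), g, tolerance = 1e-4)
  }
  ## ages above the neutral expectation clamp to zero with a warning
  expect_warning(out <- nes_from_age(2, 0.2), "neutral")
  expect_equal(out, 0)
})
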