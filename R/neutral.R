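## Fixed-segregating-sites Kingman coalescent simulator and the
## Monte-Carlo allele-frequency sampling-error calculator.  These provide
## the neutral envelopes against which observed spectra and window
## statistics are judged.

#' Simulate a Kingman coalescent genealogy
#'
#' Simulates a standard neutral genealogy for `n` haploid chromosomes.
#' While `k` lineages remain, the time to the next coalescence is
#' exponential with rate `k*(k-1)/2` (time in units of 2Ne generations) and
#' a uniformly chosen lineage pair merges.  The genealogy is represented by
#' its branch segments: for each inter-coalescent interval, every active
#' lineage contributes one segment whose descendant leaf set is recorded.
#'
#' @param n number of leaves (>= 2).
#' @return a `genealogy` object: list with `n`, `seg_len` (segment
#'   lengths), `seg_leaves` (logical matrix, segments x leaves),
#'   `interval_times` (the n-1 inter-coalescent times) and `total_length`.
#' @export
simulate_genealogy <- function(n) {
  if (n < 2) stop("need at least 2 leaves")
  leaf <- diag(TRUE, n)
  seg_len <- numeric(0)
  seg_list <- vector("list", n - 1L)
  times <- numeric(n - 1L)
  k <- n
  while (k > 1) {
    t <- rexp(1, k * (k - 1) / 2)
    times[n - k + 1L] <- t
    seg_len <- c(seg_len, rep(t, k))
    seg_list[[n - k + 1L]] <- leaf
    pick <- sample.int(k, 2L)
    merged <- leaf[pick[1L], ] | leaf[pick[2L], ]
    leaf <- rbind(leaf[-pick, , drop = FALSE], merged)
    k <- k - 1L
  }
  structure(list(n = n, seg_len = seg_len,
                 seg_leaves = do.call(rbind, seg_list),
                 interval_times = times,
                 total_length = sum(seg_len)),
            class = "genealogy")
}

#' Drop a fixed number of mutations onto a genealogy
#'
#' Places exactly `S` infinite-sites mutations on the genealogy's branch
#' segments, multinomially with probability proportional to segment length;
#' each mutation defines one segregating column whose derived carriers are
#' the leaves under the mutated segment.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param S number of segregating sites (>= 0).
#' @return an `n x S` 0/1 matrix (1 = derived).
#' @export
place_mutations <- function(genealogy, S) {
  n <- genealogy$n
  if (S == 0) return(matrix(0L, nrow = n, ncol = 0L))
  br <- sample.int(length(genealogy$seg_len), S, replace = TRUE,
                   prob = genealogy$seg_len)
  t(genealogy$seg_leaves[br, , drop = FALSE]) * 1L
}

#' Neutral envelope for Tajima's D and normalized Fay and Wu's H
#'
#' Simulates `reps` fixed-S coalescent replicates for `n` haploid
#' chromosomes and summarizes the null distributions of the two
#' statistics.  Per replicate, Tajima's D is computed on all `n`
#' chromosomes.  For normalized H, `k` chromosomes (drawn uniformly from
#' `outgroup_range`) are designated outgroup; ingroup sites are polarized
#' by strict outgroup consensus (sites with a mixed outgroup are dropped
#' for H only) and H is computed on the `n - k` ingroup chromosomes.
#' Envelope bounds are the 2.5th and 97.5th percentiles.
#'
#' @param n haploid sample size.
#' @param S segregating sites per replicate.
#' @param reps number of replicate genealogies.
#' @param outgroup_range integer values from which the per-replicate
#'   outgroup size is drawn uniformly.
#' @param seed optional RNG seed.
#' @return a `neutral_envelope` object: list with `n`, `S`, `reps`,
#'   `D` and `H` replicate vectors, `D_low`, `D_high`, `H_low`, `H_high`,
#'   `mean_folded_sfs` (proportions) and `mean_maf`.
#' @export
neutral_envelope <- function(n = 10, S = 100, reps = 10000,
                             outgroup_range = 1:5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (reps < 100) warning("fewer than 100 replicates: unstable percentiles")
  D <- numeric(reps)
  H <- rep(NA_real_, reps)
  folded_acc <- numeric(floor(n / 2))
  maf_sum <- 0
  maf_n <- 0
  for (r in seq_len(reps)) {
    gen <- simulate_genealogy(n)
    mat <- place_mutations(gen, S)
    cnt <- colSums(mat)
    D[r] <- tajimas_d(S, pairwise_pi(cnt, n), n)
    minor <- pmin(cnt, n - cnt)
    folded_acc <- folded_acc + tabulate(minor, nbins = floor(n / 2))
    maf_sum <- maf_sum + sum(minor / n)
    maf_n <- maf_n + length(minor)
    k <- if (length(outgroup_range) == 1L) outgroup_range else
      sample(outgroup_range, 1L)
    og <- sample.int(n, k)
    ing <- mat[-og, , drop = FALSE]
    cons <- colSums(mat[og, , drop = FALSE])
    keep <- cons == 0L | cons == k
    anc_derived <- cons[keep] == k   # outgroup fixed for the mutant allele
    x <- ing[, keep, drop = FALSE]
    ni <- nrow(x)
    dcount <- ifelse(anc_derived, ni - colSums(x), colSums(x))
    dcount <- as.integer(dcount[dcount > 0 & dcount < ni])
    if (length(dcount)) {
      H[r] <- fay_wu_h_norm(tabulate(dcount, nbins = ni - 1L), ni)
    }
  }
  db <- quantile(D, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  hb <- quantile(H, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(n = n, S = S, reps = reps, seed = seed,
                 D = D, H = H,
                 D_low = db[1], D_high = db[2],
                 H_low = hb[1], H_high = hb[2],
                 mean_folded_sfs = folded_acc / sum(folded_acc),
                 mean_maf = maf_sum / maf_n),
            class = "neutral_envelope")
}

#' @export
print.neutral_envelope <- function(x, ...) {
  cat(sprintf(
    "Neutral envelope (n=%d, S=%d, %d reps)\n  Tajima's D 95%%: (%.3f, %.3f)\n  normalized H 95%%: (%.3f, %.3f)\n  mean folded MAF: %.4f\n",
    x$n, x$S, x$reps, x$D_low, x$D_high, x$H_low, x$H_high, x$mean_maf))
  invisible(x)
}

#' Monte-Carlo allele-frequency sampling error
#'
#' Expected mean absolute difference between a true population allele
#' frequency and the frequency observed in a small sample of inbred lines:
#' the true frequency is uniform on (0,1), the observed count binomial, and
#' samples in which the minor allele is unobserved (count 0 or n) are
#' censored by discarding and redrawing, mirroring a detection scheme that
#' requires the minor allele in at least one line.
#'
#' With `censor = "clamp"` (the default) monomorphic observations are
#' censored by clamping the observed frequency into
#' `[1/sample_size, 1 - 1/sample_size]`; the exact expectation of the
#' clamped scheme for ten lines is 0.0963.  With `censor = "redraw"`,
#' monomorphic samples are discarded and redrawn instead (exact
#' expectation 0.1035).
#'
#' @param sample_size number of lines sampled (>= 2).
#' @param reps number of replicates.
#' @param censor `"clamp"` or `"redraw"`.
#' @param seed optional RNG seed.
#' @return list with `sample_size`, `reps` and `mean_abs_error`.
#' @export
maf_sampling_error <- function(sample_size = 10, reps = 50000,
                               censor = c("clamp", "redraw"), seed = NULL) {
  censor <- match.arg(censor)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sample_size >= 2)
  if (censor == "clamp") {
    p <- runif(reps)
    k <- pmin(pmax(rbinom(reps, sample_size, p), 1L), sample_size - 1L)
    err <- abs(k / sample_size - p)
  } else {
    err <- numeric(0)
    while (length(err) < reps) {
      m <- reps - length(err)
      p <- runif(ceiling(m * 1.3))
      k <- rbinom(length(p), sample_size, p)
      ok <- k > 0L & k < sample_size
      err <- c(err, abs(k[ok] / sample_size - p[ok]))
    }
    err <- err[seq_len(reps)]
  }
  list(sample_size = sample_size, reps = reps, censor = censor,
       mean_abs_error = mean(err))
}
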