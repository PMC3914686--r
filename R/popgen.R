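## Frequency-spectrum statistics, polarization, jackknife, intra-allelic
## diversity and the diffusion inversion from mean allele age to |NeS|.

#' Watterson's normalization constant a1 and friends
#' @noRd
harmonic <- function(n) sum(1 / seq_len(n))
harmonic2 <- function(n) sum(1 / seq_len(n)^2)

#' Site frequency spectrum and minor-allele frequencies
#'
#' Computes the folded (and, when `polarized`, unfolded) site frequency
#' spectrum from a 0/1 haplotype matrix with one row per line and one
#' column per site.  Monomorphic columns are excluded with a warning.
#'
#' @param mat integer matrix (rows = haploid lines, columns = sites); for a
#'   polarized matrix 1 means the derived allele.
#' @param polarized if `TRUE`, `mat` is derived/ancestral coded and the
#'   unfolded spectrum is returned as well.
#' @return list with `n`, `folded` (counts eta_1..eta_floor(n/2)),
#'   `unfolded` (xi_1..xi_(n-1) or NULL), per-site `maf` and `mean_maf`.
#' @export
sfs_and_maf <- function(mat, polarized = FALSE) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  poly <- cnt > 0L & cnt < n
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic site(s) excluded")
    cnt <- cnt[poly]
  }
  minor <- pmin(cnt, n - cnt)
  folded <- tabulate(minor, nbins = floor(n / 2))
  unfolded <- if (polarized) tabulate(cnt, nbins = n - 1L) else NULL
  maf <- minor / n
  list(n = n, folded = folded, unfolded = unfolded, maf = maf,
       mean_maf = mean(maf))
}

#' Mean pairwise nucleotide differences (pi) from derived-allele counts
#'
#' @param counts per-site allele counts (either allele; pi is fold-invariant).
#' @param n number of haploid lines.
#' @return total mean pairwise differences over the sites.
#' @export
pairwise_pi <- function(counts, n) {
  sum(counts * (n - counts)) / choose(n, 2)
}

#' Tajima's D
#'
#' The standard statistic contrasting mean pairwise diversity with
#' Watterson's estimator, normalized by its variance under neutrality:
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the usual constants
#' `a1, a2, b1, b2, c1, c2, e1, e2` as functions of sample size.
#'
#' @param S number of segregating sites.
#' @param pi mean pairwise differences (total over sites, not per bp).
#' @param n number of haploid lines (>= 4).
#' @return D, or `NA` when `S == 0`.
#' @export
tajimas_d <- function(S, pi, n) {
  if (n < 4) stop("tajimas_d requires n >= 4")
  if (S == 0) return(NA_real_)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Normalized Fay and Wu's H
#'
#' `H = (pi - theta_L) / sqrt(Var)` where `theta_L` is the mean derived
#' allele count `sum(i * xi_i) / (n - 1)` and the variance is the
#' standard neutral-model variance with `theta` estimated by Watterson's
#' `S/a1` and `theta^2` by `S(S-1)/(a1^2 + a2)`.
#'
#' @param xi unfolded site frequency spectrum (`xi_1 .. xi_(n-1)`, derived
#'   allele counts).
#' @param n number of haploid lines (>= 3).
#' @return normalized H, or `NA` when no segregating sites.
#' @export
fay_wu_h_norm <- function(xi, n) {
  if (length(xi) != n - 1L) stop("xi must have length n - 1 (unfolded SFS)")
  S <- sum(xi)
  if (n < 3) stop("fay_wu_h_norm requires n >= 3")
  if (S == 0) return(NA_real_)
  i <- seq_len(n - 1L)
  pi <- sum(xi * i * (n - i)) / choose(n, 2)
  theta_l <- sum(i * xi) / (n - 1)
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  theta_w <- S / a1
  theta_sq <- S * (S - 1) / (a1^2 + a2)
  bn1 <- harmonic2(n)
  v <- theta_w * (n - 2) / (6 * (n - 1)) +
    theta_sq * (18 * n^2 * (3 * n + 2) * bn1 -
                  (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (pi - theta_l) / sqrt(v)
}

#' Polarize variants with outgroup calls
#'
#' The ancestral allele is the one carried by every callable outgroup line;
#' if the callable outgroups disagree, or none is callable, the variant's
#' polarization is unknown.
#'
#' @param focal_alleles matrix or data.frame of focal-line alleles, one
#'   column per variant (any atomic coding; `NA` = uncallable).
#' @param outgroup_alleles matrix with one row per outgroup line, one column
#'   per variant.
#' @return list with `ancestral` (allele value or `NA`), `derived_minor`
#'   (logical: is the minor allele derived?), and `fraction_derived_minor`.
#' @export
polarize <- function(focal_alleles, outgroup_alleles) {
  focal_alleles <- as.matrix(focal_alleles)
  outgroup_alleles <- as.matrix(outgroup_alleles)
  stopifnot(ncol(focal_alleles) == ncol(outgroup_alleles))
  nvar <- ncol(focal_alleles)
  ancestral <- rep(NA, nvar)
  derived_minor <- rep(NA, nvar)
  for (j in seq_len(nvar)) {
    og <- outgroup_alleles[, j]
    og <- og[!is.na(og)]
    if (!length(og) || length(unique(og)) != 1L) next
    anc <- og[1]
    ancestral[j] <- anc
    al <- focal_alleles[, j]
    al <- al[!is.na(al)]
    tab <- sort(table(al), decreasing = TRUE)
    if (length(tab) < 2L) next
    minor <- names(tab)[length(tab)]
    derived_minor[j] <- minor != as.character(anc)
  }
  list(ancestral = ancestral, derived_minor = derived_minor,
       fraction_derived_minor = mean(derived_minor, na.rm = TRUE))
}

#' Delete-one jackknife confidence interval
#'
#' Recomputes a statistic over leave-one-out subsets of the sampled lines
#' and returns the jackknife mean, standard error and normal-theory 95%
#' interval.  Subsets on which the statistic is `NA` are skipped with a
#' warning.
#'
#' @param lines a vector or list of per-line units resampled over.
#' @param statistic function taking a subset of `lines` and returning a
#'   scalar.
#' @return list with `mean`, `se`, `lower`, `upper`.
#' @export
jackknife_ci <- function(lines, statistic) {
  n <- length(lines)
  if (n < 3) stop("jackknife requires at least 3 lines")
  vals <- vapply(seq_len(n),
                 function(i) statistic(lines[-i]), numeric(1))
  if (anyNA(vals)) {
    warning(sum(is.na(vals)), " leave-one-out subset(s) gave NA; skipped")
    vals <- vals[!is.na(vals)]
  }
  m <- length(vals)
  jm <- mean(vals)
  se <- sqrt((m - 1) / m * sum((vals - jm)^2))
  list(mean = jm, se = se, lower = jm - 1.96 * se, upper = jm + 1.96 * se)
}

#' Intra-allelic nucleotide diversity
#'
#' Mean pairwise difference count among the haplotypes carrying a focal
#' allele, over a fixed window, divided by the window length.  Singleton
#' alleles (one carrier) have no defined `pi_A` and return `NA`.
#'
#' @param carrier_mat 0/1 matrix of carrier haplotypes over the window's
#'   polymorphic sites (rows = carrier lines).  Sites must be callable in
#'   all carriers.
#' @param window_length haplotype window length in bp (default 500).
#' @return per-site intra-allelic diversity.
#' @export
pi_a <- function(carrier_mat, window_length = 500) {
  k <- nrow(carrier_mat)
  if (k < 2) return(NA_real_)
  if (ncol(carrier_mat) == 0L) return(0)
  cnt <- colSums(carrier_mat)
  pairwise_pi(cnt, k) / window_length
}

#' Intra-allelic diversity for a set of focal loci
#'
#' Computes [pi_a()] for each focal locus over the haplotypes of its
#' carrier lines, using the polymorphic sites inside a window centred on
#' the locus.  Singleton loci (one carrier) get `NA`.
#'
#' @param loci_pos focal positions (interval midpoints for indels).
#' @param carrier_sets list of carrier line names per locus.
#' @param geno list with `pos` (site positions) and `mat` (0/1 matrix,
#'   lines x sites, rownames = line names).
#' @param window haplotype window width in bp (default 500).
#' @return numeric vector of per-locus `pi_A`.
#' @export
pi_a_for_loci <- function(loci_pos, carrier_sets, geno, window = 500) {
  vapply(seq_along(loci_pos), function(i) {
    cc <- carrier_sets[[i]]
    if (length(cc) < 2) return(NA_real_)
    in_win <- geno$pos >= loci_pos[i] - window / 2 &
      geno$pos < loci_pos[i] + window / 2
    pi_a(geno$mat[cc, in_win, drop = FALSE], window_length = window)
  }, numeric(1))
}

#' Convert intra-allelic diversity to coalescent allele age
#'
#' Dividing a class's mean `pi_A` by the grand-mean synonymous `pi_A`
#' (the diversity accumulated over 2Ne generations for a neutral allele)
#' expresses mean allele age in units of 2Ne generations.
#'
#' @param pi_a_value mean intra-allelic diversity for the class.
#' @param grand_mean_syn grand-mean synonymous `pi_A` (> 0).
#' @return allele age T in 2Ne generations.
#' @export
allele_age <- function(pi_a_value, grand_mean_syn) {
  if (grand_mean_syn <= 0) stop("grand mean synonymous pi_A must be > 0")
  pi_a_value / grand_mean_syn
}

#' Expected mean age of a derived allele under additive selection
#'
#' Computes the diffusion expectation of the age of a derived allele
#' observed at population frequency `x`, under genic (no-dominance)
#' selection with population-scaled coefficient `gamma = Ne * s`, with age
#' in units of 2Ne generations.  The mean age equals the mean absorption
#' time at frequency 0 of the diffusion started at `x` conditioned on loss
#' (the age/extinction-time duality), and is symmetric in the sign of
#' `gamma`.  The neutral limit is the closed form
#' `-2 x log(x) / (1 - x)`.
#'
#' @param x current derived-allele frequency, in (0, 1).
#' @param gamma population-scaled selection coefficient `Ne * s` (any sign;
#'   only the magnitude matters).
#' @return expected mean allele age in 2Ne generations.
#' @export
mean_allele_age <- function(x, gamma) {
  stopifnot(x > 0, x < 1)
  g <- abs(gamma)
  if (g < 1e-9) return(-2 * x * log(x) / (1 - x))
  k <- 2 * g
  ## conditional sojourn-time densities, written in overflow-safe form
  lo <- function(xi) {
    2 * (1 - exp(-k * xi)) * (1 - exp(-k * (1 - xi))) /
      (k * (1 - exp(-k)) * xi * (1 - xi))
  }
  hi <- function(xi) {
    2 * (1 - exp(-k * x)) * exp(-k * (xi - x)) *
      (1 - exp(-k * (1 - xi)))^2 /
      (k * (1 - exp(-k)) * (1 - exp(-k * (1 - x))) * xi * (1 - xi))
  }
  i1 <- stats::integrate(lo, 0, x, rel.tol = 1e-9, subdivisions = 1000L,
                         stop.on.error = FALSE)
  i2 <- stats::integrate(hi, x, 1, rel.tol = 1e-9, subdivisions = 1000L,
                         stop.on.error = FALSE)
  i1$value + i2$value
}

#' Invert mean allele age to a selection-strength magnitude
#'
#' Finds the magnitude `gamma = |Ne*s|` at which the diffusion expectation
#' [mean_allele_age()] of an allele at frequency `x` equals the observed
#' coalescent age `T`.  Since the expected age is strictly decreasing in
#' `|gamma|`, the root is found by bisection to a relative tolerance of
#' 1e-6.  Ages older than the neutral expectation have no solution and are
#' clamped to 0 with a warning.
#'
#' @param T observed mean allele age in 2Ne generations (> 0).
#' @param x allele frequency in (0, 1).
#' @param tol relative bisection tolerance.
#' @return the selection magnitude `|Ne*s|` (>= 0).
#' @export
nes_from_age <- function(T, x, tol = 1e-6) {
  stopifnot(T > 0, x > 0, x < 1)
  neutral <- mean_allele_age(x, 0)
  if (T >= neutral) {
    if (T > neutral) {
      warning("age exceeds the neutral expectation at this frequency; ",
              "returning gamma = 0")
    }
    return(0)
  }
  hi <- 1
  while (mean_allele_age(x, hi) > T) {
    hi <- hi * 2
    if (hi > 2^20) stop("no solution: age too small for the solver range")
  }
  lo <- hi / 2
  if (hi == 1) lo <- 0
  while ((hi - lo) > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (mean_allele_age(x, mid) > T) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Experimental validation-rate arithmetic
#'
#' Percentage of conclusive assays that confirmed the in-silico call.
#'
#' @param confirmed number of confirmed calls.
#' @param conclusive number of conclusive assays.
#' @return percentage in `[0, 100]`.
#' @export
validation_rate <- function(confirmed, conclusive) {
  stopifnot(conclusive > 0, confirmed >= 0, confirmed <= conclusive)
  100 * confirmed / conclusive
}
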