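## Joint Tajima's-D / normalized-H outlier scan around polarized indels.

#' Scan indel loci for joint D/H outliers
#'
#' For each polarized indel, extracts the SNPs within a window centred on
#' the indel interval midpoint, computes Tajima's D across the focal
#' lines and normalized Fay and Wu's H on the outgroup-polarized unfolded
#' spectrum, and flags the indel as an outlier when both statistics fall
#' below the lower bounds of the neutral envelope.  Windows with no
#' usable SNPs score `NA` and are never outliers.  The candidate list
#' reported alongside retains only outliers whose derived allele is at
#' frequency `freq_min` or higher, but all scores are returned.
#'
#' @param indels table with `id`, `start`, `end`, `derived_freq` (derived
#'   allele frequency among focal lines; `NA` when unpolarized).
#' @param snp_geno list with `pos` (site positions), `mat` (0/1 matrix,
#'   focal lines x sites, 1 = minor allele), `derived_minor` (logical per
#'   site: is the minor allele derived? `NA` = unpolarized).
#' @param envelope a [neutral_envelope()].
#' @param window total window width in bp (default 10 kb).
#' @param freq_min derived-allele frequency threshold for the reported
#'   candidate list (default 0.8).
#' @return list with `scores` (per-indel D, H, outlier flag) and
#'   `candidates` (outliers at `derived_freq >= freq_min`).
#' @export
scan_indels <- function(indels, snp_geno, envelope, window = 10000,
                        freq_min = 0.8) {
  n <- nrow(snp_geno$mat)
  scores <- data.frame(id = indels$id,
                       derived_freq = indels$derived_freq,
                       D = NA_real_, H = NA_real_, outlier = FALSE)
  for (i in seq_len(nrow(indels))) {
    mid <- (indels$start[i] + indels$end[i]) / 2
    in_win <- snp_geno$pos >= mid - window / 2 &
      snp_geno$pos < mid + window / 2
    if (!any(in_win)) next
    sub <- snp_geno$mat[, in_win, drop = FALSE]
    cnt <- colSums(sub)
    poly <- cnt > 0L & cnt < n
    sub <- sub[, poly, drop = FALSE]
    cnt <- cnt[poly]
    S <- ncol(sub)
    if (S == 0L) next
    scores$D[i] <- tajimas_d(S, pairwise_pi(cnt, n), n)
    dm <- snp_geno$derived_minor[in_win][poly]
    keep <- !is.na(dm)
    if (any(keep)) {
      dcount <- ifelse(dm[keep], cnt[keep], n - cnt[keep])
      xi <- tabulate(as.integer(dcount), nbins = n - 1L)
      scores$H[i] <- fay_wu_h_norm(xi, n)
    }
    scores$outlier[i] <- !is.na(scores$D[i]) && !is.na(scores$H[i]) &&
      scores$D[i] < envelope$D_low && scores$H[i] < envelope$H_low
  }
  list(scores = scores,
       candidates = scores[scores$outlier &
                             !is.na(scores$derived_freq) &
                             scores$derived_freq >= freq_min, ])
}
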