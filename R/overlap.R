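## Genomic-context assignment and enrichment/distribution analyses for
## the retained indel set.

feat_ranges <- function(features, kinds) {
  f <- features[features$kind %in% kinds, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(f$start + 1L, f$end))
}

overlap_bp <- function(q, subj) {
  if (!length(subj)) return(rep(0L, length(q)))
  ov <- IRanges::findOverlaps(q, subj)
  w <- IRanges::width(IRanges::pintersect(
    q[S4Vectors::queryHits(ov)], subj[S4Vectors::subjectHits(ov)]))
  out <- rep(0L, length(q))
  tap <- tapply(w, S4Vectors::queryHits(ov), sum)
  out[as.integer(names(tap))] <- as.integer(tap)
  out
}

#' Assign genomic context to indels
#'
#' An indel is genic when its interval intersects an annotated gene
#' (coding or intronic components included) and a TE indel when it
#' intersects an annotated TE; the flags are independent, and a base
#' inside both contexts counts toward both.  The expected null shares are
#' the gene/TE fractions of the alignable mask, and a chi-square test of
#' independence compares the observed indel-bp composition with the
#' alignable composition at the nucleotide level.
#'
#' @param indels table with `start`, `end` (0-based half-open) and `id`.
#' @param features feature table ([load_features()] format).
#' @param mask alignable-mask data.frame (`start`, `end`).
#' @return list with `assignments` (per-indel flags and bp attribution),
#'   `composition` (observed/expected bp table) and `chisq` (htest).
#' @export
assign_context <- function(indels, features, mask) {
  if (nrow(mask) == 0L) stop("empty alignable mask")
  q <- IRanges::IRanges(indels$start + 1L, indels$end)
  gene_r <- feat_ranges(features, "gene")
  te_r <- feat_ranges(features, "TE")
  mask_r <- IRanges::reduce(IRanges::IRanges(mask$start + 1L, mask$end))
  gene_bp <- overlap_bp(q, gene_r)
  te_bp <- overlap_bp(q, te_r)
  len <- indels$end - indels$start
  assignments <- data.frame(
    id = indels$id, length = len,
    genic = gene_bp > 0L, te = te_bp > 0L,
    intergenic = gene_bp == 0L & te_bp == 0L,
    gene_bp = gene_bp, te_bp = te_bp,
    stringsAsFactors = FALSE)
  align_total <- sum(IRanges::width(mask_r))
  align_gene <- sum(IRanges::width(IRanges::intersect(mask_r, gene_r)))
  align_te <- sum(IRanges::width(IRanges::intersect(mask_r, te_r)))
  indel_total <- sum(len)
  comp <- data.frame(
    context = c("gene", "TE"),
    indel_bp = c(sum(gene_bp), sum(te_bp)),
    indel_share = c(sum(gene_bp), sum(te_bp)) / indel_total,
    alignable_bp = c(align_gene, align_te),
    expected_share = c(align_gene, align_te) / align_total)
  cs <- suppressWarnings(chisq.test(rbind(
    c(sum(gene_bp), indel_total - sum(gene_bp)),
    c(align_gene, align_total - align_gene))))
  list(assignments = assignments, composition = comp, chisq = cs)
}

#' Positional indel-density profile along normalized transcripts
#'
#' Divides each genic region (5' UTR, gene body = exons plus introns,
#' 3' UTR) into 100 equal bins and maps every indel-covered base of the
#' region to its bin via the base midpoint, strand-aware so that bin 1 is
#' always 5'.  Per-bin 95% bounds come from Binomial(n = total indel bp in
#' the region, p = 1/bins).
#'
#' @param indels table with `start`, `end`.
#' @param features feature table with UTR/exon/intron/gene rows.
#' @param bins number of bins (default 100).
#' @return named list of per-region lists (`density`, `counts`, `lower`,
#'   `upper`, `n`); regions with no covered bases have `n = 0`.
#' @export
transcript_profile <- function(indels, features, bins = 100) {
  regions <- list(
    five_prime_UTR = c("five_prime_UTR"),
    gene_body = c("exon", "intron"),
    three_prime_UTR = c("three_prime_UTR"))
  q <- IRanges::IRanges(indels$start + 1L, indels$end)
  out <- list()
  for (rn in names(regions)) {
    f <- features[features$kind %in% regions[[rn]] &
                    (is.na(features$longest) | features$longest), ,
                  drop = FALSE]
    counts <- numeric(bins)
    if (nrow(f)) {
      ## region span per transcript (gene body may span several blocks)
      sp <- split(f, f$transcript_id)
      for (tx in sp) {
        r_start <- min(tx$start); r_end <- max(tx$end)
        L <- r_end - r_start
        if (L <= 0) next
        subj <- IRanges::IRanges(r_start + 1L, r_end)
        ov <- IRanges::findOverlaps(q, subj)
        if (!length(ov)) next
        qs <- q[S4Vectors::queryHits(ov)]
        inter_s <- pmax(IRanges::start(qs) - 1L, r_start)
        inter_e <- pmin(IRanges::end(qs), r_end)
        for (k in seq_along(inter_s)) {
          pos <- seq.int(inter_s[k], inter_e[k] - 1L)
          rel <- (pos - r_start + 0.5) / L
          if (tx$strand[1] == "-") rel <- 1 - rel
          b <- pmin(pmax(ceiling(rel * bins), 1L), bins)
          counts <- counts + tabulate(b, nbins = bins)
        }
      }
    }
    n <- sum(counts)
    out[[rn]] <- list(
      counts = counts,
      density = if (n > 0) counts / n else counts,
      lower = if (n > 0) qbinom(0.025, n, 1 / bins) else NA,
      upper = if (n > 0) qbinom(0.975, n, 1 / bins) else NA,
      n = n)
  }
  out
}

#' Assign indels to a single TE family
#'
#' An indel is attributed to a TE family when at least `purity` of its
#' length is covered by TEs of that single family.
#'
#' @param indels table with `id`, `start`, `end`.
#' @param features feature table (TE rows carry `family`).
#' @param purity required covered fraction (default 0.90).
#' @return data.frame `id`, `family` (`NA` when unassigned), `fraction`.
#' @export
te_family_assign <- function(indels, features, purity = 0.90) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  tes <- features[features$kind == "TE", , drop = FALSE]
  q <- IRanges::IRanges(indels$start + 1L, indels$end)
  fam <- rep(NA_character_, nrow(indels))
  frac <- numeric(nrow(indels))
  len <- indels$end - indels$start
  for (fm in unique(tes$family)) {
    r <- IRanges::reduce(IRanges::IRanges(
      tes$start[tes$family == fm] + 1L, tes$end[tes$family == fm]))
    bp <- overlap_bp(q, r)
    f <- bp / len
    better <- f > frac
    fam[better] <- fm
    frac[better] <- f[better]
  }
  fam[frac < purity] <- NA_character_
  data.frame(id = indels$id, family = fam, fraction = frac,
             stringsAsFactors = FALSE)
}

#' TE-family enrichment among family-assigned indels
#'
#' Per family, a two-sided Fisher's exact test on the 2x2 table of
#' (indels in family vs other families) against (annotated TEs in family
#' vs others), with Bonferroni correction over the families tested.
#'
#' @param assignments output of [te_family_assign()].
#' @param features feature table (reference TE composition).
#' @return data.frame per family: `observed`, `expected`, `fold`, `p`,
#'   `p_bonferroni`.
#' @export
te_family_enrichment <- function(assignments, features) {
  tes <- features[features$kind == "TE", , drop = FALSE]
  assigned <- assignments[!is.na(assignments$family), , drop = FALSE]
  fams <- sort(unique(tes$family))
  n_assigned <- nrow(assigned)
  n_te <- nrow(tes)
  res <- lapply(fams, function(fm) {
    obs <- sum(assigned$family == fm)
    ref <- sum(tes$family == fm)
    expct <- n_assigned * ref / n_te
    p <- fisher.test(matrix(c(obs, n_assigned - obs,
                              ref, n_te - ref), 2))$p.value
    data.frame(family = fm, observed = obs, expected = expct,
               fold = if (expct > 0) obs / expct else NA_real_, p = p)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * length(fams))
  res
}

#' Gene-family (paralog cluster) size comparison and enrichment
#'
#' Compares the paralog-cluster sizes of indel-bearing genes with the
#' genome-wide cluster sizes (Mann-Whitney U) and tests each family for
#' enrichment of indel genes (Fisher's exact, Bonferroni-corrected).
#'
#' @param indel_genes gene ids bearing an indel.
#' @param gene_families data.frame `gene_id`, `family`.
#' @return list with `median_all`, `median_indel`, `utest` (htest) and
#'   `families` (per-family enrichment table).
#' @export
gene_family_enrichment <- function(indel_genes, gene_families) {
  fam_size <- table(gene_families$family)
  size_all <- as.integer(fam_size[gene_families$family])
  idx <- gene_families$gene_id %in% indel_genes
  size_indel <- size_all[idx]
  ut <- suppressWarnings(wilcox.test(size_indel, size_all))
  n_genes <- nrow(gene_families)
  n_hit <- sum(idx)
  fams <- names(fam_size)
  res <- lapply(fams, function(fm) {
    in_fam <- gene_families$family == fm
    obs <- sum(idx & in_fam)
    expct <- n_hit * sum(in_fam) / n_genes
    p <- fisher.test(matrix(c(obs, n_hit - obs,
                              sum(in_fam) - obs,
                              n_genes - n_hit - sum(in_fam) + obs), 2))$p.value
    data.frame(family = fm, family_size = sum(in_fam), observed = obs,
               expected = expct, p = p)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, res$p * length(fams))
  list(median_all = stats::median(size_all),
       median_indel = stats::median(size_indel),
       utest = ut, families = res)
}

#' Coverage-normalized indel/SNP window-density correlation
#'
#' Partitions the genome into non-overlapping windows, tallies indels and
#' SNPs per window, normalizes both tallies by total read coverage in the
#' window, and fits a least-squares line.
#'
#' @param indel_pos indel positions (e.g. interval midpoints).
#' @param snp_pos SNP positions.
#' @param coverage per-window total read coverage (recycled if scalar).
#' @param genome_length reference length.
#' @param window window size in bp (default 500 kb).
#' @return list with `r`, `slope`, `df`, `p`, `windows` table.
#' @export
window_density_correlation <- function(indel_pos, snp_pos, coverage,
                                       genome_length, window = 5e5) {
  if (window <= 0) stop("window must be positive")
  n_win <- ceiling(genome_length / window)
  if (n_win < 3) stop("need at least 3 windows")
  iw <- tabulate(pmin(floor(indel_pos / window) + 1L, n_win), nbins = n_win)
  sw <- tabulate(pmin(floor(snp_pos / window) + 1L, n_win), nbins = n_win)
  cov <- rep_len(coverage, n_win)
  x <- sw / cov
  y <- iw / cov
  fit <- lm(y ~ x)
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), slope = unname(coef(fit)[2]),
       df = unname(ct$parameter), p = ct$p.value,
       windows = data.frame(window = seq_len(n_win), indels = iw,
                            snps = sw, coverage = cov))
}

#' Indel size by minor-allele-frequency class
#'
#' Class means of indel size per MAF class plus Welch's one-way ANOVA
#' (unequal variances, Satterthwaite degrees of freedom).  Classes with
#' fewer than two members are skipped.
#'
#' @param sizes indel sizes (bp).
#' @param maf minor-allele frequencies (classes such as 0.1 .. 0.5).
#' @return list with `means` (per-class) and `anova` (htest from
#'   [stats::oneway.test()]).
#' @export
size_by_maf <- function(sizes, maf) {
  cls <- factor(maf)
  keep_cls <- names(which(table(cls) >= 2))
  keep <- cls %in% keep_cls
  sizes <- sizes[keep]; cls <- droplevels(cls[keep])
  means <- tapply(sizes, cls, mean)
  aov <- oneway.test(sizes ~ cls, var.equal = FALSE)
  list(means = means, anova = aov)
}
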