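## End-to-end orchestration on a configuration: simulate -> call SVs ->
## filter -> call SNPs -> population-genetic summaries -> context/
## enrichment -> neutral envelope -> selection scan.

#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with every analysis threshold
#' (all defaulting to the pipeline's canonical values: mapping quality 29,
#' discordant insert 1,000 bp, cluster window 225 bp, minimum support 3,
#' minimum SV size 1,000 bp, depth percentile 10, density percentile 90,
#' coverage band 10-90, SNP depth 3-25, majority 0.75, pi_A window 500 bp,
#' scan window 10 kb, derived-frequency threshold 0.8).
#'
#' @param sim a [sim_config()].
#' @param min_mapq,min_insert,cluster_window,min_support,min_size,
#'   depth_pct,density_pct,band,snp_depth,majority,pi_a_window,
#'   scan_window,freq_min analysis thresholds.
#' @param envelope_reps,envelope_S neutral-envelope settings.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_mapq = 29, min_insert = 1000,
                            cluster_window = 225, min_support = 3,
                            min_size = 1000, depth_pct = 0.10,
                            density_pct = 0.90, band = c(0.10, 0.90),
                            snp_depth = c(3, 25), majority = 0.75,
                            pi_a_window = 500, scan_window = 10000,
                            freq_min = 0.8,
                            envelope_reps = 10000, envelope_S = 100) {
  cfg <- as.list(environment())
  stopifnot(min_mapq > 0, min_insert > 0, cluster_window > 0,
            min_support >= 1, min_size > 0,
            depth_pct > 0, depth_pct < 1, density_pct > 0, density_pct < 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-data pipeline
#'
#' Executes every stage on a fresh synthetic population and returns a
#' report: planted truth, candidate attrition through the filter cascade,
#' precision/recall against truth, the SNP table, indel/SNP frequency
#' summaries, context and TE-family enrichment, the neutral envelope and
#' the joint D/H selection scan.  Deterministic given the seeds in the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return a `pipeline_report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  sim_cfg <- config$sim

  say("stage 1/8: generating truth")
  truth <- generate_truth(sim_cfg)
  say("stage 2/8: simulating read pairs")
  sim <- simulate_read_pairs(truth, sim_cfg)

  say("stage 3/8: discordant SV calling")
  svs <- call_svs(sim$pairs, min_mapq = config$min_mapq,
                  min_insert = config$min_insert,
                  window = config$cluster_window,
                  min_support = config$min_support)

  say("stage 4/8: filter cascade")
  index <- discordant_density_index(svs$pool, truth$genome_length,
                                    pct = config$density_pct)
  filt <- apply_filter_cascade(svs$candidates, sim$depth, index,
                               reference_line = truth$reference_line,
                               min_size = config$min_size,
                               depth_pct = config$depth_pct,
                               band = config$band)
  retained <- filt$retained[filt$retained$sv_type == "deletion", ]
  eval_res <- evaluate_calls(retained, truth)

  say("stage 5/8: SNP calling")
  pile <- simulate_pileups(truth, sim_cfg)
  calls <- lapply(pile, function(p) {
    cbind(p[, c("chrom", "pos")],
          call_bases(p[, c("A", "C", "G", "T")],
                     min_depth = config$snp_depth[1],
                     max_depth = config$snp_depth[2],
                     majority = config$majority))
  })
  snp_tab <- build_snp_table(calls[truth$focal_lines],
                             focal_lines = truth$focal_lines)

  say("stage 6/8: population-genetic summaries")
  og_allele <- vapply(truth$outgroup_lines, function(acc) {
    calls[[acc]]$base[match(snp_tab$pos, calls[[acc]]$pos)]
  }, character(nrow(snp_tab)))
  focal_al <- t(as.matrix(snp_tab[, truth$focal_lines, with = FALSE]))
  pol <- polarize(focal_al, t(og_allele))
  ## lines x sites 0/1 matrix, 1 = any non-major allele (minor pooled)
  geno_raw <- as.matrix(snp_tab[, truth$focal_lines, with = FALSE])
  geno_mat <- t(geno_raw != snp_tab$major) * 1L
  rownames(geno_mat) <- truth$focal_lines

  indel_maf <- retained_maf(retained, truth$focal_lines)
  snp_summary <- list(count = nrow(snp_tab), mean_maf = mean(snp_tab$maf),
                      fraction_derived_minor = pol$fraction_derived_minor)
  indel_summary <- list(count = nrow(retained),
                        median_size = stats::median(retained$size),
                        mean_maf = mean(indel_maf))

  say("stage 7/8: context and enrichment")
  ctx <- assign_context(retained, truth$features, truth$mask)
  te_asn <- te_family_assign(retained, truth$features)
  te_enr <- te_family_enrichment(te_asn, truth$features)
  smaf <- if (nrow(retained) >= 10 && length(unique(indel_maf)) > 1) {
    size_by_maf(retained$size, indel_maf)
  } else NULL

  ## strength of selection: pi_A by class, allele age, |NeS| at x = 0.2
  effects <- annotate_effect(snp_tab, truth$features, truth$reference)
  sel <- selection_strength(snp_tab, effects, geno_mat, retained, ctx,
                            truth$focal_lines,
                            pi_a_window = config$pi_a_window)

  say("stage 8/8: neutral envelope and selection scan")
  env <- neutral_envelope(n = length(truth$focal_lines),
                          S = config$envelope_S,
                          reps = config$envelope_reps,
                          seed = sim_cfg$seed + 3L)
  indel_pol <- polarize_indels(retained, truth)
  scan <- scan_indels(indel_pol, list(pos = snp_tab$pos, mat = geno_mat,
                                      derived_minor = pol$derived_minor),
                      env, window = config$scan_window,
                      freq_min = config$freq_min)

  structure(list(
    config = config, truth = truth,
    candidates = svs$candidates, verdicts = filt$verdicts,
    retained = retained, evaluation = eval_res,
    attrition = data.frame(
      stage = c("candidates", "retained"),
      deletions = c(sum(svs$candidates$sv_type == "deletion"),
                    nrow(retained)),
      inversions = c(sum(svs$candidates$sv_type == "inversion"),
                     sum(filt$retained$sv_type == "inversion")),
      transpositions = c(sum(svs$candidates$sv_type == "transposition"),
                         sum(filt$retained$sv_type == "transposition"))),
    snp_table = snp_tab, snp_summary = snp_summary,
    indel_summary = indel_summary, size_by_maf = smaf,
    context = ctx, te_enrichment = te_enr,
    selection_strength = sel,
    envelope = env, scan = scan
  ), class = "pipeline_report")
}

## pi_A by mutational class (synonymous / nonsynonymous SNPs and genic
## deletions) with coalescent-age conversion and diffusion inversion at
## the focal frequency class x = 0.2
selection_strength <- function(snp_tab, effects, geno_mat, retained, ctx,
                               focal_lines, pi_a_window = 500,
                               focal_freq = 0.2) {
  n <- length(focal_lines)
  geno <- list(pos = snp_tab$pos, mat = geno_mat)
  snp_carriers <- lapply(seq_len(nrow(snp_tab)), function(i) {
    focal_lines[geno_mat[, i] == 1L]
  })
  snp_pia <- pi_a_for_loci(snp_tab$pos, snp_carriers, geno,
                           window = pi_a_window)
  syn <- effects == "synonymous"
  nonsyn <- effects == "nonsynonymous"
  grand_mean_syn <- mean(snp_pia[syn], na.rm = TRUE)
  cls_mean <- function(pia, freq, x) {
    v <- pia[!is.na(pia) & abs(freq - x) < 1e-9]
    if (length(v)) mean(v) else NA_real_
  }
  genic_ids <- ctx$assignments$id[ctx$assignments$genic]
  gen_del <- retained[retained$id %in% genic_ids, ]
  del_carriers <- lapply(strsplit(gen_del$accessions, ","), intersect,
                         focal_lines)
  del_pia <- if (nrow(gen_del)) {
    pi_a_for_loci((gen_del$start + gen_del$end) / 2, del_carriers, geno,
                  window = pi_a_window)
  } else numeric(0)
  del_freq <- vapply(del_carriers, function(cc) min(length(cc),
                                                    n - length(cc)) / n,
                     numeric(1))
  classes <- data.frame(
    class = c("genic_deletion", "nonsynonymous", "synonymous"),
    pi_a = c(cls_mean(del_pia, del_freq, focal_freq),
             cls_mean(snp_pia[nonsyn], snp_tab$maf[nonsyn], focal_freq),
             cls_mean(snp_pia[syn], snp_tab$maf[syn], focal_freq)))
  classes$T <- classes$pi_a / grand_mean_syn
  classes$nes <- vapply(classes$T, function(Tt) {
    if (is.na(Tt) || Tt <= 0) NA_real_
    else suppressWarnings(nes_from_age(Tt, focal_freq))
  }, numeric(1))
  list(grand_mean_syn_pi_a = grand_mean_syn, classes = classes,
       focal_freq = focal_freq)
}

## MAF of retained deletions from their supporting accession sets
retained_maf <- function(retained, focal_lines) {
  if (!nrow(retained)) return(numeric(0))
  vapply(strsplit(retained$accessions, ","), function(cc) {
    k <- sum(cc %in% focal_lines)
    min(k, length(focal_lines) - k) / length(focal_lines)
  }, numeric(1))
}

## polarize retained deletion calls against truth outgroup haplotypes:
## matched planted deletions inherit the truth's ancestral state
polarize_indels <- function(retained, truth) {
  n <- length(truth$focal_lines)
  derived_freq <- rep(NA_real_, nrow(retained))
  if (nrow(truth$deletions) && nrow(retained)) {
    q <- IRanges::IRanges(retained$start + 1L, retained$end)
    s <- IRanges::IRanges(truth$deletions$start + 1L, truth$deletions$end)
    ov <- IRanges::findOverlaps(q, s, select = "first")
    for (i in seq_len(nrow(retained))) {
      j <- ov[i]
      if (is.na(j)) next
      carriers <- strsplit(retained$accessions[i], ",")[[1]]
      k <- sum(carriers %in% truth$focal_lines)
      derived_freq[i] <- if (truth$deletions$derived[j]) k / n
                         else (n - k) / n
    }
  }
  data.frame(id = retained$id, start = retained$start, end = retained$end,
             derived_freq = derived_freq, stringsAsFactors = FALSE)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Synthetic SV population-genomics pipeline report\n")
  cat(sprintf("  planted deletions: %d; candidates: %d; retained: %d\n",
              nrow(x$truth$deletions),
              sum(x$candidates$sv_type == "deletion"), nrow(x$retained)))
  cat(sprintf("  precision %.3f, recall %.3f\n",
              x$evaluation$precision, x$evaluation$recall))
  cat(sprintf("  SNPs called in all lines: %d (mean MAF %.3f)\n",
              x$snp_summary$count, x$snp_summary$mean_maf))
  cat(sprintf("  envelope D (%.2f, %.2f), H (%.2f, %.2f)\n",
              x$envelope$D_low, x$envelope$D_high,
              x$envelope$H_low, x$envelope$H_high))
  cat(sprintf("  scan outliers: %d (candidates at freq >= %.1f: %d)\n",
              sum(x$scan$scores$outlier, na.rm = TRUE),
              x$config$freq_min, nrow(x$scan$candidates)))
  invisible(x)
}
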