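## The candidate filter cascade.  Every filter follows the all-accession
## rule: one failing supporting accession rejects the candidate outright.

#' Reference-accession filter
#'
#' Rejects a candidate when the resequenced reference accession is among
#' its supporting accessions: aligned against itself, the reference line
#' can only produce discordant pairs in regions of unreliable alignment.
#'
#' @param candidate one candidate row.
#' @param reference_line reference accession name.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
reference_accession_filter <- function(candidate, reference_line) {
  !(reference_line %in% strsplit(candidate$accessions, ",")[[1]])
}

#' Minimum-size filter
#'
#' Retains only SVs of at least `min_size` bp (default 1,000).
#'
#' @param candidate one candidate row.
#' @param min_size minimum size in bp.
#' @export
min_size_filter <- function(candidate, min_size = 1000) {
  candidate$size >= min_size
}

#' Deletion read-depth filter
#'
#' For a deletion candidate, every carrier's mean read depth over the
#' predicted interval must lie within the lowest `pct` quantile of that
#' carrier's genome-wide (per-tile) depth distribution: a homozygous
#' deletion should leave the interval essentially uncovered.
#'
#' @param candidate one deletion candidate row.
#' @param profiles a [depth_profiles()] object.
#' @param pct depth percentile (default 0.10).
#' @export
deletion_depth_filter <- function(candidate, profiles, pct = 0.10) {
  carriers <- strsplit(candidate$accessions, ",")[[1]]
  for (acc in carriers) {
    thr <- depth_quantile(profiles, acc, pct)
    d <- interval_mean_depth(profiles, acc, candidate$start, candidate$end)
    if (d > thr) return(FALSE)
  }
  TRUE
}

#' Coverage-band filter for inversions and transpositions
#'
#' Mean depth over the SV interval must remain between the `band[1]` and
#' `band[2]` genome-wide depth quantiles for every supporting accession,
#' to avoid regions of unusually sparse or dense coverage.
#'
#' @param candidate one candidate row.
#' @param profiles a [depth_profiles()] object.
#' @param band two quantiles (default `c(0.10, 0.90)`).
#' @export
coverage_band_filter <- function(candidate, profiles,
                                 band = c(0.10, 0.90)) {
  iv <- candidate_interval(candidate)
  for (acc in strsplit(candidate$accessions, ",")[[1]]) {
    lo <- depth_quantile(profiles, acc, band[1])
    hi <- depth_quantile(profiles, acc, band[2])
    d <- interval_mean_depth(profiles, acc, iv[1], iv[2])
    if (d < lo || d > hi) return(FALSE)
  }
  TRUE
}

## interval used for depth statistics: the predicted interval for
## deletions, the full anchor span otherwise
candidate_interval <- function(candidate) {
  if (candidate$sv_type == "deletion") {
    c(candidate$start, candidate$end)
  } else {
    c(candidate$left_lo, max(candidate$right_hi, candidate$left_lo + 1L))
  }
}

#' Build the discordant-density background index
#'
#' Counts pooled discordant anchor positions (both anchors of every pair)
#' in non-overlapping `window`-bp tiles genome-wide and records the high
#' quantile of the tile counts.  Candidates whose endpoints sit in windows
#' with more background discordant reads than this quantile are rejected
#' by [discordant_density_filter()].
#'
#' @param pool pooled discordant table.
#' @param genome_length reference length.
#' @param window window size in bp (default 5,000).
#' @param pct background quantile (default 0.90).
#' @return a `discordant_index` list.
#' @export
discordant_density_index <- function(pool, genome_length, window = 5000,
                                     pct = 0.90) {
  anchors <- sort(c(pool$left_start, pool$right_start))
  anchor_pair <- c(pool$pair_id, pool$pair_id)[order(
    c(pool$left_start, pool$right_start))]
  tiles <- tabulate(pmin(anchors %/% window + 1L,
                         ceiling(genome_length / window)),
                    nbins = ceiling(genome_length / window))
  structure(list(anchors = anchors, anchor_pair = anchor_pair,
                 window = window,
                 threshold = quantile(tiles, pct, names = FALSE)),
            class = "discordant_index")
}

#' Discordant-density filter
#'
#' For each candidate endpoint, counts pooled discordant anchors in a
#' window centred on the endpoint, discounting the anchors of the
#' candidate's own supporting pairs; the candidate fails when either count
#' exceeds the genome-wide background threshold of the index.
#'
#' @param candidate one candidate row.
#' @param index a [discordant_density_index()].
#' @export
discordant_density_filter <- function(candidate, index) {
  own <- strsplit(candidate$pair_ids, ",")[[1]]
  half <- index$window / 2
  for (e in c(candidate$start, candidate$end)) {
    lo <- e - half
    hi <- e + half
    i1 <- findInterval(lo - 0.5, index$anchors) + 1L
    i2 <- findInterval(hi - 0.5, index$anchors)
    cnt <- if (i2 >= i1) {
      sum(!(index$anchor_pair[i1:i2] %in% own))
    } else 0L
    if (cnt > index$threshold) return(FALSE)
  }
  TRUE
}

#' Apply the full filter cascade
#'
#' Applies, in order: reference-accession filter, minimum-size filter,
#' the type-specific depth filter (deletion depth for deletions, coverage
#' band for inversions/transpositions), and the discordant-density
#' filter.  A verdict row is recorded for every input candidate; the
#' retained set is the candidates passing all applicable filters.
#'
#' @param candidates candidate table from [make_candidates()].
#' @param profiles a [depth_profiles()] object covering all supporting
#'   accessions.
#' @param index a [discordant_density_index()].
#' @param reference_line reference accession name.
#' @param min_size minimum SV size (default 1000).
#' @param depth_pct deletion-depth percentile (default 0.10).
#' @param band coverage band (default `c(0.10, 0.90)`).
#' @return list with `retained` (candidate table) and `verdicts` (one row
#'   per input candidate with per-filter pass/fail and `final`).
#' @export
apply_filter_cascade <- function(candidates, profiles, index,
                                 reference_line, min_size = 1000,
                                 depth_pct = 0.10, band = c(0.10, 0.90)) {
  n <- nrow(candidates)
  v <- data.table::data.table(
    id = candidates$id,
    ref_accession = logical(n), min_size = logical(n),
    deletion_depth = NA, coverage_band = NA,
    discordant_density = logical(n), final = logical(n))
  v$deletion_depth <- as.logical(v$deletion_depth)
  v$coverage_band <- as.logical(v$coverage_band)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    v$ref_accession[i] <- reference_accession_filter(cand, reference_line)
    v$min_size[i] <- min_size_filter(cand, min_size)
    if (cand$sv_type == "deletion") {
      v$deletion_depth[i] <- deletion_depth_filter(cand, profiles, depth_pct)
    } else {
      v$coverage_band[i] <- coverage_band_filter(cand, profiles, band)
    }
    v$discordant_density[i] <- discordant_density_filter(cand, index)
    v$final[i] <- v$ref_accession[i] && v$min_size[i] &&
      (is.na(v$deletion_depth[i]) || v$deletion_depth[i]) &&
      (is.na(v$coverage_band[i]) || v$coverage_band[i]) &&
      v$discordant_density[i]
  }
  list(retained = candidates[v$final, ], verdicts = v)
}
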