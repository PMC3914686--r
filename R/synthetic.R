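## Synthetic population generator: inbred genomes with planted deletions,
## SNPs, gene/TE annotation, and per-accession read-pair alignment records
## with controlled noise.  Reads are not simulated as sequences; alignment
## records are simulated directly, since the pipeline consumes alignments.

TE_FAMILIES <- c(MULE = 0.18, Gypsy = 0.17, Copia = 0.12, hAT = 0.10,
                 CACTA = 0.09, LINE = 0.08, helitron = 0.08, TRIM = 0.07,
                 LARD = 0.06, Harbinger = 0.05)

## neutral folded spectrum over minor-allele counts 1..5 for n = 10 lines
neutral_folded_law <- function(n = 10) {
  i <- seq_len(floor(n / 2))
  p <- 1 / i + ifelse(i < n - i, 1 / (n - i), 0)
  p / sum(p)
}

#' Simulation configuration
#'
#' Builds the configuration for the synthetic population.  Defaults mirror
#' the study design the package emulates: ten fully homozygous focal lines
#' (one of which, `line00`, is the reference accession), two outgroup
#' lines, paired-end libraries with mean outer insert 275.8 bp (SD 28.8),
#' 75 bp reads, planted deletions of 1-200 kb whose sizes follow a
#' truncated log-normal with median 2,563 bp, and a minor-allele-count law
#' over counts 1..5.
#'
#' @param seed RNG seed used by [generate_truth()] and
#'   [simulate_read_pairs()].
#' @param n_focal_lines,n_outgroup_lines population design.
#' @param genome_length reference length in bp (single chromosome).
#' @param n_genes,n_tes number of gene models and TE annotations placed.
#' @param deletion_count number of planted deletions.
#' @param deletion_size_range allowed deletion sizes in bp.
#' @param deletion_size_meanlog,deletion_size_sdlog log-normal size law
#'   (truncated to `deletion_size_range`).
#' @param deletion_frequency_law probabilities over minor-allele counts
#'   1..5; default the neutral folded spectrum.
#' @param deletion_derived_fraction fraction of deletions whose deletion
#'   allele is derived (outgroups carry the presence allele).
#' @param snp_density SNPs per bp of reference.
#' @param snp_derived_fraction fraction of SNPs whose minor allele is
#'   derived.
#' @param coverage_mean mean sequence depth per line.
#' @param insert_mean,insert_sd outer insert-span distribution (bp).
#' @param read_len read length (bp).
#' @param chimera_rate baseline fraction of pairs given a random distal
#'   second anchor.
#' @param repeat_hotspot_count,hotspot_width,hotspot_chimera_multiplier
#'   repeat-like regions with elevated chimera rates.
#' @param mapq_low_fraction fraction of pairs in which one mate's mapping
#'   quality falls below the usable threshold of 29.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_focal_lines = 10,
                       n_outgroup_lines = 2,
                       genome_length = 5e6,
                       n_genes = 250,
                       n_tes = 500,
                       deletion_count = 40,
                       deletion_size_range = c(1000, 200000),
                       deletion_size_meanlog = log(2563),
                       deletion_size_sdlog = 1.3,
                       deletion_frequency_law = neutral_folded_law(10),
                       deletion_derived_fraction = 0.72,
                       snp_density = 0.01,
                       snp_derived_fraction = 0.62,
                       coverage_mean = 8,
                       insert_mean = 275.8,
                       insert_sd = 28.8,
                       read_len = 75,
                       chimera_rate = 2e-4,
                       repeat_hotspot_count = 5,
                       hotspot_width = 5000,
                       hotspot_chimera_multiplier = 25,
                       mapq_low_fraction = 0.15) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_focal_lines >= 2, cfg$n_outgroup_lines >= 1,
            cfg$insert_sd > 0, cfg$deletion_count >= 0,
            all(cfg$deletion_frequency_law >= 0),
            cfg$deletion_size_range[1] < cfg$deletion_size_range[2])
  cfg$deletion_frequency_law <-
    cfg$deletion_frequency_law / sum(cfg$deletion_frequency_law)
  structure(cfg, class = "sim_config")
}

## non-overlapping placement of widths on [margin, G - margin)
place_intervals <- function(widths, genome_length, occupied = NULL,
                            margin = 10000, gap = 0, max_tries = 200) {
  occ <- if (is.null(occupied)) IRanges::IRanges() else occupied
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, margin, genome_length - margin - w))
      cand <- IRanges::IRanges(s + 1L - gap, s + w + gap)
      if (!length(IRanges::findOverlaps(cand, occ))) {
        starts[i] <- s
        occ <- c(occ, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("genome too small to place requested intervals (failed at item ",
           i, " of width ", w, ")")
    }
  }
  starts
}

#' Generate the population ground truth
#'
#' Deterministically (given `config$seed`) builds a reference sequence,
#' gene/TE annotation, repeat hotspots, an alignable mask (genome minus
#' hotspots), planted deletions with carrier sets drawn from the
#' frequency law, SNPs, and outgroup haplotypes defining the ancestral
#' state of every variant.  The reference accession `line00` never carries
#' a deletion (the reference was built from it), so deletion carriers are
#' drawn from the nine other focal lines.
#'
#' @param config a [sim_config()].
#' @return a `population_truth` list.
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  G <- as.integer(config$genome_length)
  chrom <- "chr1"
  focal <- sprintf("line%02d", seq_len(config$n_focal_lines) - 1L)
  outg <- sprintf("og%02d", seq_len(config$n_outgroup_lines))

  reference <- Biostrings::DNAString(paste(
    sample(c("A", "C", "G", "T"), G, replace = TRUE), collapse = ""))

  ## repeat hotspots and the alignable mask
  hs_starts <- if (config$repeat_hotspot_count > 0) {
    place_intervals(rep(config$hotspot_width, config$repeat_hotspot_count), G)
  } else integer(0)
  hotspots <- data.frame(chrom = rep(chrom, length(hs_starts)),
                         start = hs_starts,
                         end = hs_starts + config$hotspot_width)
  mask <- span_setdiff(0L, G, hotspots$start, hotspots$end)
  mask <- data.frame(chrom = chrom, start = mask$start, end = mask$end)

  ## gene models: UTRs + coding exons (lengths multiples of 3) + introns
  occ <- IRanges::IRanges(hotspots$start + 1L, hotspots$end)
  genes <- make_gene_models(config$n_genes, G, occ, chrom)
  occ <- c(occ, IRanges::IRanges(genes$gene_tab$start + 1L,
                                 genes$gene_tab$end))

  te_len <- pmin(pmax(round(stats::rlnorm(config$n_tes, log(800), 0.7)),
                      100), 10000)
  te_start <- place_intervals(te_len, G, occ)
  te_fam <- sample(names(TE_FAMILIES), config$n_tes, replace = TRUE,
                   prob = TE_FAMILIES)
  te_tab <- data.frame(chrom = chrom, start = te_start,
                       end = te_start + te_len, kind = "TE",
                       family = te_fam, transcript_id = NA_character_,
                       gene_id = NA_character_, strand = "+", longest = NA,
                       stringsAsFactors = FALSE)

  features <- rbind(genes$feature_tab, te_tab)

  ## planted deletions: truncated log-normal sizes, disjoint placement
  if (config$deletion_count > 0) {
    sz <- integer(0)
    while (length(sz) < config$deletion_count) {
      cand <- round(stats::rlnorm(config$deletion_count * 3,
                                  config$deletion_size_meanlog,
                                  config$deletion_size_sdlog))
      cand <- cand[cand >= config$deletion_size_range[1] &
                     cand <= config$deletion_size_range[2]]
      sz <- c(sz, cand)
    }
    sz <- sz[seq_len(config$deletion_count)]
    dstart <- place_intervals(sz, G, occupied = IRanges::IRanges(
      hotspots$start + 1L, hotspots$end), gap = 1000L)
    o <- order(dstart)
    dstart <- dstart[o]; sz <- sz[o]
    m <- sample(seq_along(config$deletion_frequency_law),
                config$deletion_count, replace = TRUE,
                prob = config$deletion_frequency_law)
    carriers <- lapply(m, function(k) sort(sample(focal[-1L], k)))
    derived <- runif(config$deletion_count) < config$deletion_derived_fraction
    deletions <- data.table::data.table(
      id = sprintf("del%04d", seq_along(sz)),
      chrom = chrom, start = as.integer(dstart),
      end = as.integer(dstart + sz), size = as.integer(sz),
      m = m, carriers = vapply(carriers, paste, "", collapse = ","),
      derived = derived)
  } else {
    deletions <- data.table::data.table(
      id = character(), chrom = character(), start = integer(),
      end = integer(), size = integer(), m = integer(),
      carriers = character(), derived = logical())
  }

  ## SNPs
  n_snp <- round(config$snp_density * G)
  pos <- sort(sample.int(G - 2L, n_snp))
  refb <- strsplit(as.character(Biostrings::extractAt(
    reference, IRanges::IRanges(pos + 1L, pos + 1L))), "")
  refb <- vapply(refb, `[`, "", 1L)
  altb <- vapply(refb, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                          1L), "")
  ms <- sample(seq_along(config$deletion_frequency_law), n_snp,
               replace = TRUE, prob = config$deletion_frequency_law)
  snp_carriers <- lapply(ms, function(k) sort(sample(focal[-1L], k)))
  snp_derived <- runif(n_snp) < config$snp_derived_fraction
  snps <- data.table::data.table(
    id = sprintf("snp%06d", seq_len(n_snp)),
    chrom = chrom, pos = as.integer(pos), ref = refb, alt = altb,
    m = ms, carriers = vapply(snp_carriers, paste, "", collapse = ","),
    derived = snp_derived)

  structure(list(
    config = config, chrom = chrom, genome_length = G,
    reference = reference, features = features,
    gene_families = genes$gene_families,
    hotspots = hotspots, mask = mask,
    deletions = deletions, snps = snps,
    focal_lines = focal, outgroup_lines = outg,
    reference_line = focal[1L]
  ), class = "population_truth")
}

## internal: n gene models with 1-2 transcripts each
make_gene_models <- function(n_genes, G, occupied, chrom) {
  if (n_genes == 0) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), kind = character(),
                        family = character(), transcript_id = character(),
                        gene_id = character(), strand = character(),
                        longest = logical(), stringsAsFactors = FALSE)
    return(list(feature_tab = empty, gene_tab = empty,
                gene_families = data.frame(gene_id = character(),
                                           family = character())))
  }
  n_exon <- sample(2:5, n_genes, replace = TRUE)
  utr5 <- sample(150:300, n_genes, replace = TRUE)
  utr3 <- sample(150:300, n_genes, replace = TRUE)
  exon_lens <- lapply(n_exon, function(k) 3L * sample(50:200, k, TRUE))
  intron_lens <- lapply(n_exon, function(k) sample(100:1000, k - 1L, TRUE))
  span <- utr5 + utr3 + vapply(exon_lens, sum, 0) +
    vapply(intron_lens, sum, 0)
  gstart <- place_intervals(span, G, occupied)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  ## skewed paralog-family assignment (a few big families, many singletons)
  n_fam <- max(3L, round(n_genes / 6))
  fam_w <- 1 / seq_len(n_fam)^0.7
  fam <- paste0("fam", sample(seq_len(n_fam), n_genes, TRUE, prob = fam_w))

  rows <- vector("list", n_genes * 20L)
  ri <- 0L
  add <- function(start, end, kind, tx, gid, std) {
    ri <<- ri + 1L
    rows[[ri]] <<- data.frame(chrom = chrom, start = start, end = end,
                              kind = kind, family = NA_character_,
                              transcript_id = tx, gene_id = gid,
                              strand = std, longest = NA,
                              stringsAsFactors = FALSE)
  }
  second_tx <- runif(n_genes) < 0.1
  for (i in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", i)
    s <- gstart[i]; e <- s + span[i]
    add(s, e, "gene", NA_character_, gid, strand[i])
    tx1 <- paste0(gid, ".1")
    ## physical layout left-to-right: utr5|exon1|intron1|...|utrl3 for "+"
    cur <- s
    blocks <- list(c("five_prime_UTR", utr5[i]))
    for (k in seq_len(n_exon[i])) {
      blocks[[length(blocks) + 1L]] <- c("exon", exon_lens[[i]][k])
      if (k < n_exon[i]) {
        blocks[[length(blocks) + 1L]] <- c("intron", intron_lens[[i]][k])
      }
    }
    blocks[[length(blocks) + 1L]] <- c("three_prime_UTR", utr3[i])
    if (strand[i] == "-") {
      blocks <- rev(blocks)  # 5' UTR sits at the right end on minus strand
    }
    for (b in blocks) {
      w <- as.integer(b[2])
      add(cur, cur + w, b[1], tx1, gid, strand[i])
      cur <- cur + w
    }
    if (second_tx[i] && n_exon[i] > 2L) {
      ## shorter transcript skipping the last exon (same span bounds)
      tx2 <- paste0(gid, ".2")
      tx1_rows <- which(vapply(rows[seq_len(ri)], function(r)
        !is.null(r) && identical(r$transcript_id, tx1) &&
          r$kind == "exon", logical(1)))
      drop <- tx1_rows[length(tx1_rows)]
      for (j in setdiff(tx1_rows, drop)) {
        r <- rows[[j]]
        add(r$start, r$end, "exon", tx2, gid, strand[i])
      }
    }
  }
  feature_tab <- do.call(rbind, rows[seq_len(ri)])
  ## flag longest transcript per gene by exon length
  mr <- data.frame(id = unique(stats::na.omit(feature_tab$transcript_id)))
  feature_tab <- flag_longest_transcripts(feature_tab, mr)
  gene_tab <- feature_tab[feature_tab$kind == "gene", ]
  list(feature_tab = feature_tab, gene_tab = gene_tab,
       gene_families = data.frame(
         gene_id = sprintf("gene%04d", seq_len(n_genes)), family = fam,
         stringsAsFactors = FALSE))
}

#' Carrier sets as a logical matrix
#' @param truth a [generate_truth()] result.
#' @param what `"deletions"` or `"snps"`.
#' @return logical matrix, focal lines x variants.
#' @export
carrier_matrix <- function(truth, what = c("deletions", "snps")) {
  what <- match.arg(what)
  tab <- truth[[what]]
  carr <- strsplit(tab$carriers, ",")
  m <- matrix(FALSE, length(truth$focal_lines), nrow(tab),
              dimnames = list(truth$focal_lines, tab$id))
  for (j in seq_along(carr)) m[carr[[j]], j] <- TRUE
  m
}

#' Simulate read-pair alignment records and depth profiles
#'
#' For each accession, fragments are drawn along that line's genome
#' (reference minus carried deletions) with outer insert spans
#' `Normal(insert_mean, insert_sd)`, then mapped back to reference
#' coordinates.  Pairs spanning a carried deletion acquire an insert span
#' inflated by the deleted length with unchanged inward orientation;
#' reads crossing a deletion junction are dropped (they would be clipped
#' or unmapped by an aligner).  Noise: a `chimera_rate` fraction of pairs
#' (multiplied inside repeat hotspots) receive a random distal second
#' anchor, and a `mapq_low_fraction` of pairs get one mate's mapping
#' quality below 29.  The reference accession is simulated against its own
#' genome, so its discordant pairs arise only from noise.
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [sim_config()].
#' @param accessions which lines to simulate; defaults to the focal lines.
#' @return list with `pairs` (one read-pair table, all accessions) and
#'   `depth` (a depth-profile object, see [depth_profiles()]).
#' @export
simulate_read_pairs <- function(truth, config = truth$config,
                                accessions = truth$focal_lines) {
  set.seed(config$seed + 1L)
  G <- truth$genome_length
  rl <- config$read_len
  del_mat <- carrier_matrix(truth, "deletions")
  hot <- truth$hotspots
  out <- vector("list", length(accessions))
  for (ai in seq_along(accessions)) {
    acc <- accessions[ai]
    dels <- if (acc %in% rownames(del_mat) && ncol(del_mat)) {
      truth$deletions[del_mat[acc, ], ]
    } else truth$deletions[0, ]
    if (acc %in% truth$outgroup_lines && nrow(truth$deletions)) {
      dels <- truth$deletions[!truth$deletions$derived, ]
    }
    cum <- c(0L, cumsum(dels$size))
    Lline <- G - sum(dels$size)
    npair <- round(config$coverage_mean * Lline / (2 * rl))
    w <- pmax(round(rnorm(npair, config$insert_mean, config$insert_sd)),
              2L * rl + 5L)
    s <- floor(runif(npair, 0, Lline - w))
    ## sample->reference offset; deletion starts in sample coordinates
    dstart_sample <- dels$start - cum[-length(cum)]
    idx_l1 <- findInterval(s, dstart_sample)
    idx_l2 <- findInterval(s + rl - 1L, dstart_sample)
    idx_r1 <- findInterval(s + w - rl, dstart_sample)
    idx_r2 <- findInterval(s + w - 1L, dstart_sample)
    keep <- idx_l1 == idx_l2 & idx_r1 == idx_r2
    s <- s[keep]; w <- w[keep]
    off_l <- cum[idx_l1[keep] + 1L]
    off_r <- cum[idx_r1[keep] + 1L]
    np <- length(s)
    dt <- data.table::data.table(
      accession = acc,
      chrom_left = truth$chrom,
      left_start = as.integer(s + off_l),
      left_end = as.integer(s + off_l + rl),
      strand_left = "+",
      mapq_left = 60L,
      chrom_right = truth$chrom,
      right_start = as.integer(s + w - rl + off_r),
      right_end = as.integer(s + w + off_r),
      strand_right = "-",
      mapq_right = 60L
    )
    ## chimera noise, concentrated in repeat hotspots
    p_chim <- rep(config$chimera_rate, np)
    if (nrow(hot)) {
      in_hot <- interval_hits(dt$left_start, dt$left_end, hot$start, hot$end)
      p_chim[in_hot] <- p_chim[in_hot] * config$hotspot_chimera_multiplier
    }
    chim <- runif(np) < p_chim
    if (any(chim)) {
      nch <- sum(chim)
      rpos <- floor(runif(nch, 0, G - rl))
      data.table::set(dt, which(chim), "right_start", as.integer(rpos))
      data.table::set(dt, which(chim), "right_end", as.integer(rpos + rl))
      data.table::set(dt, which(chim), "strand_right",
                      sample(c("+", "-"), nch, TRUE))
    }
    ## low mapping quality noise (one mate per affected pair)
    lowq <- runif(np) < config$mapq_low_fraction
    if (any(lowq)) {
      side <- sample(c("mapq_left", "mapq_right"), sum(lowq), TRUE)
      qv <- sample(0:28, sum(lowq), TRUE)
      for (sd_ in c("mapq_left", "mapq_right")) {
        rows <- which(lowq)[side == sd_]
        data.table::set(dt, rows, sd_, as.integer(qv[side == sd_]))
      }
    }
    dt[, insert_span := pmax(right_end, left_end) -
         pmin(left_start, right_start)]
    dt[, pair_id := paste0(acc, ":", .I)]
    dt[, flag := make_sam_flag(strand_left, strand_right)]
    out[[ai]] <- normalize_pair_table(dt)
  }
  pairs <- data.table::rbindlist(out)
  list(pairs = pairs, depth = depth_profiles(pairs, G, accessions))
}

## which intervals [s,e) hit any of the [hs,he) set
interval_hits <- function(s, e, hs, he) {
  if (!length(hs)) return(rep(FALSE, length(s)))
  q <- IRanges::IRanges(s + 1L, e)
  subj <- IRanges::IRanges(hs + 1L, he)
  IRanges::overlapsAny(q, subj)
}

#' Per-accession read-depth profiles on 1 kb tiles
#'
#' Mean depth per non-overlapping 1 kb tile, computed from read starts
#' (each read contributes `read_len` bases to its starting tile).  The
#' genome-wide depth distribution of an accession is the distribution of
#' its tile means.
#'
#' @param pairs a read-pair table.
#' @param genome_length reference length.
#' @param accessions accession order for the profile columns.
#' @param tile_width tile size in bp.
#' @param read_len read length used to convert counts to depth.
#' @return a `depth_profiles` object: list with `tile_width`, `depth`
#'   (tiles x accessions matrix) and `genome_length`.
#' @export
depth_profiles <- function(pairs, genome_length,
                           accessions = sort(unique(pairs$accession)),
                           tile_width = 1000, read_len = 75) {
  n_tiles <- ceiling(genome_length / tile_width)
  mat <- matrix(0, n_tiles, length(accessions),
                dimnames = list(NULL, accessions))
  for (acc in accessions) {
    p <- pairs[accession == acc]
    starts <- c(p$left_start, p$right_start)
    tl <- pmin(starts %/% tile_width + 1L, n_tiles)
    cnt <- tabulate(tl, nbins = n_tiles)
    mat[, acc] <- cnt * read_len / tile_width
  }
  structure(list(tile_width = tile_width, depth = mat,
                 genome_length = genome_length),
            class = "depth_profiles")
}

#' Depth quantile for one accession
#' @param profiles a [depth_profiles()] object.
#' @param accession accession name.
#' @param p probability.
#' @export
depth_quantile <- function(profiles, accession, p) {
  quantile(profiles$depth[, accession], p, names = FALSE)
}

#' Mean depth over an interval for one accession
#' @param profiles a [depth_profiles()] object.
#' @param accession accession name.
#' @param start,end 0-based half-open interval.
#' @export
interval_mean_depth <- function(profiles, accession, start, end) {
  tw <- profiles$tile_width
  if (start < 0 || end > nrow(profiles$depth) * tw || start >= end) {
    stop("interval outside the depth profile")
  }
  t1 <- start %/% tw + 1L
  t2 <- (end - 1L) %/% tw + 1L
  tiles <- t1:t2
  lo <- pmax(start, (tiles - 1L) * tw)
  hi <- pmin(end, tiles * tw)
  sum(profiles$depth[tiles, accession] * (hi - lo)) / (end - start)
}

#' Score calls against the planted truth
#'
#' A call matches a planted deletion when their reciprocal overlap is at
#' least `reciprocal_overlap_threshold` and the call's supporting
#' accessions include at least half of the true carriers.
#'
#' @param candidates deletion candidates (`start`, `end`, `accessions`).
#' @param truth a [generate_truth()] result.
#' @param reciprocal_overlap_threshold in (0, 1].
#' @return list with `precision` (NA when nothing was called), `recall`,
#'   and a per-variant `matches` table.
#' @export
evaluate_calls <- function(candidates, truth,
                           reciprocal_overlap_threshold = 0.5) {
  if (reciprocal_overlap_threshold <= 0 || reciprocal_overlap_threshold > 1) {
    stop("reciprocal overlap threshold must be in (0, 1]")
  }
  tr <- truth$deletions
  nc <- nrow(candidates)
  nt <- nrow(tr)
  if (nt == 0L) {
    return(list(precision = if (nc) 0 else NA_real_, recall = NA_real_,
                matches = data.frame()))
  }
  matched_call <- logical(nc)
  matched_truth <- logical(nt)
  best <- rep(NA_character_, nc)
  if (nc) {
    q <- IRanges::IRanges(candidates$start + 1L, candidates$end)
    s <- IRanges::IRanges(tr$start + 1L, tr$end)
    ov <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    inter <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
    ro <- pmin(inter / IRanges::width(q[qh]), inter / IRanges::width(s[sh]))
    ok <- ro >= reciprocal_overlap_threshold
    for (ii in which(ok)) {
      i <- qh[ii]; j <- sh[ii]
      tcar <- strsplit(tr$carriers[j], ",")[[1]]
      ccar <- strsplit(candidates$accessions[i], ",")[[1]]
      if (length(intersect(tcar, ccar)) >= ceiling(length(tcar) / 2)) {
        matched_call[i] <- TRUE
        matched_truth[j] <- TRUE
        best[i] <- tr$id[j]
      }
    }
  }
  list(
    precision = if (nc) sum(matched_call) / nc else NA_real_,
    recall = sum(matched_truth) / nt,
    matches = data.frame(truth_id = tr$id, size = tr$size,
                         recovered = matched_truth)
  )
}

#' Simulate per-accession pileup counts at variant sites
#'
#' For every SNP position (and accession) draws a Poisson read depth and
#' attributes the reads to the accession's true allele, with an optional
#' per-read error rate spread uniformly over the three other bases.
#' Positions falling inside a deletion carried by the accession get zero
#' depth.  Outgroup accessions are included: they carry the ancestral
#' allele of every variant.
#'
#' @param truth a [generate_truth()] result.
#' @param config the same [sim_config()].
#' @param accessions lines to simulate (default focal + outgroup).
#' @param error_rate per-read miscall probability (default 0).
#' @return named list of data.frames (`chrom`, `pos`, `depth`, `A`, `C`,
#'   `G`, `T`) per accession.
#' @export
simulate_pileups <- function(truth, config = truth$config,
                             accessions = c(truth$focal_lines,
                                            truth$outgroup_lines),
                             error_rate = 0) {
  set.seed(config$seed + 2L)
  snps <- truth$snps
  dels <- truth$deletions
  del_mat <- carrier_matrix(truth, "deletions")
  snp_mat <- carrier_matrix(truth, "snps")
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (acc in accessions) {
    is_outgroup <- acc %in% truth$outgroup_lines
    allele <- if (is_outgroup) {
      ifelse(snps$derived, snps$ref, snps$alt)
    } else {
      ifelse(snp_mat[acc, ], snps$alt, snps$ref)
    }
    ## zero depth where the line lacks the sequence
    if (nrow(dels)) {
      carried <- if (is_outgroup) !dels$derived else del_mat[acc, ]
      deleted <- interval_hits(snps$pos, snps$pos + 1L,
                               dels$start[carried], dels$end[carried])
    } else deleted <- rep(FALSE, nrow(snps))
    depth <- rpois(nrow(snps), config$coverage_mean)
    depth[deleted] <- 0L
    cnt <- matrix(0L, nrow(snps), 4L, dimnames = list(NULL, bases))
    err <- if (error_rate > 0) rbinom(nrow(snps), depth, error_rate) else 0L
    main <- depth - err
    ai <- match(allele, bases)
    cnt[cbind(seq_len(nrow(snps)), ai)] <- main
    if (any(err > 0)) {
      for (i in which(err > 0)) {
        other <- setdiff(seq_len(4L), ai[i])
        spread <- tabulate(sample(other, err[i], TRUE), nbins = 4L)
        cnt[i, ] <- cnt[i, ] + spread
      }
    }
    out[[acc]] <- data.frame(chrom = snps$chrom, pos = snps$pos,
                             depth = depth, cnt,
                             stringsAsFactors = FALSE)
  }
  out
}

#' Write the synthetic data set to disk in standard formats
#'
#' Reference FASTA, annotation GFF3, alignable-mask BED, one pair TSV per
#' accession and the truth tables as TSV.
#'
#' @param truth a [generate_truth()] result.
#' @param sim a [simulate_read_pairs()] result.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_data <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(truth$reference)
  names(ref) <- truth$chrom
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))
  export_features_gff3(truth$features, file.path(dir, "annotation.gff3"))
  mask <- truth$mask
  writeLines(sprintf("%s\t%d\t%d", mask$chrom, mask$start, mask$end),
             file.path(dir, "alignable_mask.bed"))
  for (acc in unique(sim$pairs$accession)) {
    write_pair_tsv(sim$pairs[accession == acc],
                   file.path(dir, paste0(acc, ".pairs.tsv")))
  }
  data.table::fwrite(truth$deletions, file.path(dir, "truth_deletions.tsv"),
                     sep = "\t")
  data.table::fwrite(truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t")
  invisible(dir)
}

## feature table -> GFF3 via rtracklayer (kind mapped back to GFF3 types)
export_features_gff3 <- function(features, path) {
  f <- features
  type <- ifelse(f$kind == "TE", "transposable_element",
                 ifelse(f$kind == "intron", "intron", f$kind))
  ## emit mRNA rows so that load_features() can rebuild transcripts
  tx <- unique(stats::na.omit(f$transcript_id))
  tx_rows <- do.call(rbind, lapply(tx, function(t) {
    sub <- f[!is.na(f$transcript_id) & f$transcript_id == t, ]
    data.frame(chrom = sub$chrom[1], start = min(sub$start),
               end = max(sub$end), type = "mRNA", strand = sub$strand[1],
               ID = t, Parent = sub$gene_id[1], family = NA_character_,
               stringsAsFactors = FALSE)
  }))
  base_rows <- data.frame(
    chrom = f$chrom, start = f$start, end = f$end, type = type,
    strand = f$strand,
    ID = ifelse(f$kind == "gene", f$gene_id, NA_character_),
    Parent = ifelse(f$kind %in% c("exon", "five_prime_UTR",
                                  "three_prime_UTR", "intron"),
                    f$transcript_id, NA_character_),
    family = f$family, stringsAsFactors = FALSE)
  allr <- rbind(base_rows[base_rows$type != "intron", ], tx_rows)
  gr <- GenomicRanges::GRanges(
    seqnames = allr$chrom,
    ranges = IRanges::IRanges(allr$start + 1L, allr$end),
    strand = allr$strand)
  gr$type <- allr$type
  gr$ID <- allr$ID
  gr$Parent <- allr$Parent
  gr$family <- allr$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
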