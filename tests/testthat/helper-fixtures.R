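## Shared fixtures and independent brute-force oracles.

## a read-pair row in internal coordinates
pair_row <- function(accession = "lineA", chrom = "chr1",
                     left_start = 100L, left_end = 175L,
                     right_start = 400L, right_end = 475L,
                     strand_left = "+", strand_right = "-",
                     mapq_left = 60L, mapq_right = 60L,
                     id = paste0(accession, ":", left_start)) {
  data.table::data.table(
    accession = accession, chrom_left = chrom, left_start = left_start,
    left_end = left_end, strand_left = strand_left, mapq_left = mapq_left,
    chrom_right = chrom, right_start = right_start, right_end = right_end,
    strand_right = strand_right, mapq_right = mapq_right,
    insert_span = max(right_end, left_end) - min(left_start, right_start),
    pair_id = id, flag = 1L)
}

pair_table <- function(...) data.table::rbindlist(list(...))

## deletion-signal pairs (75 bp reads) at given left/right anchor starts
del_pairs <- function(lefts, rights, acc = "lineA") {
  do.call(pair_table, lapply(seq_along(lefts), function(i) {
    pair_row(accession = acc, left_start = lefts[i],
             left_end = lefts[i] + 75L, right_start = rights[i],
             right_end = rights[i] + 75L,
             id = paste0(acc, ":", i, ":", lefts[i]))
  }))
}

## brute-force mean pairwise differences by explicit double loop
brute_pi <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / choose(n, 2)
}

## brute-force Tajima's D written straight from the constant definitions
brute_tajima <- function(mat) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  S <- sum(cnt > 0 & cnt < n)
  if (S == 0) return(NA_real_)
  pi <- brute_pi(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

## a tiny depth-profile object built by hand:
## tiles is a matrix (n_tiles x accessions) of mean tile depths
fake_profiles <- function(tiles, tile_width = 1000) {
  structure(list(tile_width = tile_width, depth = tiles,
                 genome_length = nrow(tiles) * tile_width),
            class = "depth_profiles")
}

## small synthetic configuration for fast tests (overrides win)
small_sim_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, genome_length = 1e6, n_genes = 60,
                   n_tes = 120, deletion_count = 12,
                   deletion_size_range = c(1000, 50000),
                   snp_density = 0.01, repeat_hotspot_count = 2)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

noise_free_config <- function(seed = 5, ...) {
  defaults <- list(seed = seed, genome_length = 1e6, n_genes = 40,
                   n_tes = 80, deletion_count = 10,
                   deletion_size_range = c(1000, 30000),
                   snp_density = 0.005, chimera_rate = 0,
                   repeat_hotspot_count = 0, mapq_low_fraction = 0)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
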