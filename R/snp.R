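## Pileup-style base calling for homozygous inbred lines and population
## SNP table construction with coding-effect annotation.

#' Call a base from pileup counts
#'
#' A base is called at a site when coverage is between `min_depth` and
#' `max_depth` (inclusive) and strictly more than `majority` of the reads
#' show the same nucleotide; otherwise the site is missing with a reason
#' (`low_depth`, `high_depth`, `no_majority`).  Vectorized over sites.
#'
#' @param counts matrix (sites x 4) of A, C, G, T read counts.
#' @param min_depth,max_depth coverage bounds (defaults 3 and 25; a
#'   designated high-coverage accession may use a higher `max_depth`).
#' @param majority required read fraction (strict inequality; default
#'   0.75).
#' @return data.frame with `depth`, `base` (NA when missing) and `reason`.
#' @export
call_bases <- function(counts, min_depth = 3, max_depth = 25,
                       majority = 0.75) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative base counts")
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  topn <- counts[cbind(seq_len(nrow(counts)), top)]
  base <- c("A", "C", "G", "T")[top]
  frac_ok <- topn > majority * depth
  reason <- rep(NA_character_, nrow(counts))
  reason[depth < min_depth] <- "low_depth"
  reason[depth > max_depth] <- "high_depth"
  reason[depth >= min_depth & depth <= max_depth & !frac_ok] <- "no_majority"
  base[!is.na(reason)] <- NA_character_
  data.frame(depth = depth, base = base, reason = reason,
             stringsAsFactors = FALSE)
}

#' Build the population SNP table
#'
#' Combines per-accession site calls and keeps the sites that are callable
#' in every focal line and polymorphic among them.  Multi-allelic sites
#' are retained with all non-major alleles pooled as the minor allele and
#' flagged.
#'
#' @param calls named list (one element per accession) of data.frames with
#'   columns `chrom`, `pos`, `base` (NA = uncallable).
#' @param focal_lines accessions that must all be callable.
#' @return `data.table` with `chrom`, `pos`, one allele column per focal
#'   line, `major`, `minor`, `minor_count`, `maf`, `multiallelic`.
#' @export
build_snp_table <- function(calls, focal_lines = names(calls)) {
  stopifnot(all(focal_lines %in% names(calls)))
  base_mat <- NULL
  key <- NULL
  for (acc in focal_lines) {
    x <- data.table::as.data.table(calls[[acc]])[, .(chrom, pos, base)]
    data.table::setnames(x, "base", acc)
    base_mat <- if (is.null(base_mat)) x else
      merge(base_mat, x, by = c("chrom", "pos"), all = TRUE)
  }
  al <- as.matrix(base_mat[, ..focal_lines])
  complete <- rowSums(is.na(al)) == 0L
  n_allele <- apply(al, 1L, function(a) length(unique(a[!is.na(a)])))
  keep <- complete & n_allele >= 2L
  base_mat <- base_mat[keep]
  al <- al[keep, , drop = FALSE]
  n <- length(focal_lines)
  info <- t(apply(al, 1L, function(a) {
    tab <- sort(table(a), decreasing = TRUE)
    major <- names(tab)[1]
    minor_count <- n - tab[[1]]
    c(major = major, minor = names(tab)[2], minor_count = minor_count,
      multi = length(tab) > 2L)
  }))
  base_mat[, `:=`(major = info[, "major"], minor = info[, "minor"],
                  minor_count = as.integer(info[, "minor_count"]),
                  multiallelic = as.logical(info[, "multi"]))]
  base_mat[, maf := minor_count / n]
  base_mat[]
}

#' Annotate the coding effect of a SNP
#'
#' Recomputes the codon containing each SNP on the longest transcript's
#' coding frame (strand-aware) and classifies the substitution as
#' `synonymous` or `nonsynonymous`; positions outside coding exons are
#' `noncoding`.  Transcripts whose coding length is not a multiple of 3
#' are skipped with a warning.
#'
#' @param snps data.frame with `chrom`, `pos`, `ref`-style major and
#'   `minor` allele columns (`major`, `minor`).
#' @param features feature table from [load_features()] (or truth
#'   features): coding exons must have `kind == "exon"`.
#' @param reference a `DNAString` of the reference chromosome.
#' @return character vector of effects aligned with `snps` rows.
#' @export
annotate_effect <- function(snps, features, reference) {
  exons <- features[features$kind == "exon" & !is.na(features$longest) &
                      features$longest, ]
  effect <- rep("noncoding", nrow(snps))
  if (!nrow(exons)) return(effect)
  code <- Biostrings::GENETIC_CODE
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, ]
    ex <- ex[order(ex$start), ]
    cds_len <- sum(ex$end - ex$start)
    if (cds_len %% 3L != 0L) {
      warning("coding length of ", tx, " not a multiple of 3; skipped")
      next
    }
    hit <- which(snps$pos >= min(ex$start) & snps$pos < max(ex$end))
    if (!length(hit)) next
    ## genomic position -> position in the spliced CDS (plus strand order)
    cum <- c(0L, cumsum(ex$end - ex$start))
    strand <- ex$strand[1]
    cds_seq <- paste(vapply(seq_len(nrow(ex)), function(i) {
      as.character(Biostrings::subseq(reference, ex$start[i] + 1L,
                                      ex$end[i]))
    }, ""), collapse = "")
    if (strand == "-") {
      cds_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    }
    for (s in hit) {
      p <- snps$pos[s]
      i <- which(p >= ex$start & p < ex$end)
      if (!length(i)) next
      cds_pos0 <- cum[i] + (p - ex$start[i])       # plus-strand CDS offset
      if (strand == "-") cds_pos0 <- cds_len - 1L - cds_pos0
      ref_b <- substr(cds_seq, cds_pos0 + 1L, cds_pos0 + 1L)
      major <- as.character(snps$major[s])
      minor <- as.character(snps$minor[s])
      alt_g <- if (major == toupper(strand_base(ref_b, strand))) minor
               else major
      alt_b <- strand_base(alt_g, strand)
      codon_i <- cds_pos0 %/% 3L
      codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      mut <- codon
      substr(mut, cds_pos0 %% 3L + 1L, cds_pos0 %% 3L + 1L) <- alt_b
      effect[s] <- if (code[[codon]] == code[[mut]]) "synonymous"
                   else "nonsynonymous"
    }
  }
  effect
}

## complement a base when on the minus strand
strand_base <- function(b, strand) {
  if (strand == "+") return(b)
  c(A = "T", C = "G", G = "C", T = "A")[[b]]
}
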