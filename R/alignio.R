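## I/O boundary for the pipeline.  All coordinates inside the package are
## 0-based half-open; SAM, GFF3 and VCF-like output use their native 1-based
## conventions and are converted exactly once, here.

#' Column names of the 12-column pair TSV dialect
#' @export
PAIR_TSV_COLUMNS <- c(
  "accession",
  "chrom_left", "left_start", "left_end", "strand_left", "mapq_left",
  "chrom_right", "right_start", "right_end", "strand_right", "mapq_right",
  "insert_span"
)

#' Load paired-end alignment records
#'
#' Reads one accession's read-pair alignments into the package's internal
#' read-pair table.  Two dialects are supported: `"pair_tsv"`, a documented
#' 12-column tab-separated table already in 0-based half-open coordinates
#' (columns `accession`, `chrom_left`, `left_start`, `left_end`,
#' `strand_left`, `mapq_left`, `chrom_right`, `right_start`, `right_end`,
#' `strand_right`, `mapq_right`, `insert_span`), and `"sam_bam"`, a SAM or
#' BAM file whose 1-based positions are converted on read.  Pairs with an
#' unmapped mate are skipped and counted.
#'
#' The returned table has one row per pair with, additionally, a namespaced
#' `pair_id` and the SAM `flag` (reconstructed for TSV input).  When both
#' mates map to the same chromosome the left anchor is the one with the
#' smaller start.
#'
#' @param path file to read.
#' @param dialect `"pair_tsv"` or `"sam_bam"`.
#' @param accession accession label; defaults to the file name without
#'   extension.  Ignored for `pair_tsv` input, which carries its own
#'   `accession` column.
#' @return a `data.table` of read pairs; the number of skipped
#'   orphan/unmapped pairs is attached as attribute `"skipped"`.
#' @export
load_alignments <- function(path, dialect = c("pair_tsv", "sam_bam"),
                            accession = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "pair_tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    if (!identical(names(dt), PAIR_TSV_COLUMNS)) {
      stop("pair TSV must have exactly the 12 documented columns, got: ",
           paste(names(dt), collapse = ", "))
    }
    bad <- which(dt$left_start >= dt$left_end | dt$right_start >= dt$right_end |
                   dt$insert_span < 0)
    if (length(bad)) {
      stop("malformed pair record at line ", bad[1] + 1L,
           " (empty anchor interval or negative insert span)")
    }
    dt[, pair_id := paste0(accession, ":", .I)]
    dt[, flag := make_sam_flag(strand_left, strand_right)]
    attr(dt, "skipped") <- 0L
    return(normalize_pair_table(dt))
  }
  load_alignments_sam(path, accession)
}

## strand encoding of a proper primary pair into the two per-mate flags,
## reported here as the first-mate flag only (0x1 paired + 0x2 both mapped
## implied; 0x10/0x20 strand bits)
make_sam_flag <- function(strand_left, strand_right) {
  1L + 64L +
    ifelse(strand_left == "-", 16L, 0L) +
    ifelse(strand_right == "-", 32L, 0L)
}

load_alignments_sam <- function(path, accession = NULL) {
  if (is.null(accession)) {
    accession <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth",
             "mapq", "mrnm", "mpos", "isize"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table::data.table(
    qname = x$qname, flag = x$flag, chrom = as.character(x$rname),
    strand = as.character(x$strand), pos = x$pos, qwidth = x$qwidth,
    mapq = x$mapq, isize = x$isize
  )
  unmapped <- bitwAnd(dt$flag, 4L) != 0L | bitwAnd(dt$flag, 8L) != 0L |
    is.na(dt$pos)
  n_pairs_in <- length(unique(dt$qname))
  dt <- dt[!unmapped]
  dt <- dt[, if (.N == 2L) .SD, by = qname]
  skipped <- n_pairs_in - length(unique(dt$qname))
  if (nrow(dt) == 0L) {
    out <- empty_pair_table()
    attr(out, "skipped") <- skipped
    return(out)
  }
  dt[, ord := order(pos), by = qname]
  first <- dt[dt[, .I[which.min(pos)], by = qname]$V1]
  second <- dt[dt[, .I[which.max(pos)], by = qname]$V1]
  out <- data.table::data.table(
    accession = accession,
    chrom_left = first$chrom,
    left_start = first$pos - 1L,
    left_end = first$pos - 1L + first$qwidth,
    strand_left = first$strand,
    mapq_left = first$mapq,
    chrom_right = second$chrom,
    right_start = second$pos - 1L,
    right_end = second$pos - 1L + second$qwidth,
    strand_right = second$strand,
    mapq_right = second$mapq,
    insert_span = abs(first$isize),
    pair_id = paste0(accession, ":", first$qname),
    flag = first$flag
  )
  attr(out, "skipped") <- skipped
  normalize_pair_table(out)
}

empty_pair_table <- function() {
  data.table::data.table(
    accession = character(), chrom_left = character(),
    left_start = integer(), left_end = integer(),
    strand_left = character(), mapq_left = integer(),
    chrom_right = character(), right_start = integer(),
    right_end = integer(), strand_right = character(),
    mapq_right = integer(), insert_span = integer(),
    pair_id = character(), flag = integer()
  )
}

## enforce the left-anchor-is-leftmost invariant for same-chromosome pairs
normalize_pair_table <- function(dt) {
  swap <- dt$chrom_left == dt$chrom_right & dt$left_start > dt$right_start
  if (any(swap)) {
    cols_l <- c("left_start", "left_end", "strand_left", "mapq_left")
    cols_r <- c("right_start", "right_end", "strand_right", "mapq_right")
    tmp <- dt[swap, ..cols_l]
    for (i in seq_along(cols_l)) {
      data.table::set(dt, which(swap), cols_l[i], dt[swap][[cols_r[i]]])
      data.table::set(dt, which(swap), cols_r[i], tmp[[i]])
    }
  }
  dt[]
}

#' Write a read-pair table in the 12-column TSV dialect
#'
#' @param pairs a read-pair table.
#' @param path output file.
#' @export
write_pair_tsv <- function(pairs, path) {
  data.table::fwrite(pairs[, PAIR_TSV_COLUMNS, with = FALSE], path,
                     sep = "\t")
  invisible(path)
}

#' Load gene and transposable-element annotation from GFF3
#'
#' Imports a GFF3 annotation and converts it to the package's flat feature
#' table (0-based half-open coordinates).  Recognised types are `gene`,
#' `mRNA`, `exon`, `five_prime_UTR`, `three_prime_UTR` and TE rows (type
#' `transposable_element` or any type listed in `te_types`).  Introns are
#' synthesized per transcript as the transcript span minus its exons and
#' UTRs, and the longest transcript of each gene is flagged.  Children
#' extending outside their parent span are clamped with a warning.
#'
#' @param path GFF3 file.
#' @param te_types GFF3 `type` values treated as transposable elements.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `kind`,
#'   `family`, `transcript_id`, `gene_id`, `strand`, `longest`.
#' @export
load_features <- function(path,
                          te_types = c("transposable_element", "repeat_region")) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = as.character(gr$type),
    strand = as.character(GenomicRanges::strand(gr)),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = if (!is.null(gr$Parent)) {
      vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    } else NA_character_,
    family = if (!is.null(gr$family)) as.character(gr$family)
             else NA_character_,
    stringsAsFactors = FALSE
  )
  is_te <- df$type %in% te_types
  tes <- df[is_te, ]
  te_rows <- if (nrow(tes)) {
    data.frame(chrom = tes$chrom, start = tes$start, end = tes$end,
               kind = "TE", family = tes$family,
               transcript_id = NA_character_, gene_id = NA_character_,
               strand = tes$strand, longest = NA, stringsAsFactors = FALSE)
  } else NULL

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  parts <- df[df$type %in% c("exon", "five_prime_UTR", "three_prime_UTR"), ]
  rows <- list()
  if (nrow(genes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = genes$chrom, start = genes$start, end = genes$end,
      kind = "gene", family = genes$family, transcript_id = NA_character_,
      gene_id = genes$id, strand = genes$strand, longest = NA,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(mrnas))) {
    tx <- mrnas[i, ]
    kids <- parts[parts$parent == tx$id, ]
    clamped <- pmax(kids$start, tx$start) != kids$start |
      pmin(kids$end, tx$end) != kids$end
    if (any(clamped)) {
      warning("features of transcript ", tx$id,
              " extend outside the transcript span; clamping")
      kids$start <- pmax(kids$start, tx$start)
      kids$end <- pmin(kids$end, tx$end)
    }
    if (nrow(kids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = kids$chrom, start = kids$start, end = kids$end,
        kind = ifelse(kids$type == "exon", "exon", kids$type),
        family = NA_character_, transcript_id = tx$id,
        gene_id = tx$parent, strand = kids$strand, longest = NA,
        stringsAsFactors = FALSE)
    }
    introns <- span_setdiff(tx$start, tx$end, kids$start, kids$end)
    if (nrow(introns)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom, start = introns$start, end = introns$end,
        kind = "intron", family = NA_character_, transcript_id = tx$id,
        gene_id = tx$parent, strand = tx$strand, longest = NA,
        stringsAsFactors = FALSE)
    }
  }
  feat <- do.call(rbind, c(rows, list(te_rows)))
  flag_longest_transcripts(feat, mrnas)
}

## complement of a set of 0-based half-open intervals within [lo, hi)
span_setdiff <- function(lo, hi, starts, ends) {
  if (!length(starts)) return(data.frame(start = lo, end = hi))
  d <- IRanges::setdiff(IRanges::IRanges(lo + 1L, hi),
                        IRanges::IRanges(starts + 1L, ends))
  data.frame(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

## longest transcript per gene measured as summed exon+UTR length
flag_longest_transcripts <- function(feat, mrnas) {
  if (is.null(feat)) return(feat)
  part <- feat$kind %in% c("exon", "five_prime_UTR", "three_prime_UTR")
  if (!any(part)) return(feat)
  lens <- tapply(feat$end[part] - feat$start[part],
                 feat$transcript_id[part], sum)
  tx_gene <- unique(feat[part, c("transcript_id", "gene_id")])
  tx_gene$len <- lens[tx_gene$transcript_id]
  keep <- unlist(lapply(split(tx_gene, tx_gene$gene_id), function(g) {
    g$transcript_id[which.max(g$len)]
  }))
  feat$longest <- ifelse(is.na(feat$transcript_id), NA,
                         feat$transcript_id %in% keep)
  feat
}

#' Write structural-variant calls
#'
#' Writes finalized SV candidates as BED (0-based half-open; the name column
#' is `type:support`), a VCF-like text file (1-based `POS`, `END`/`SVLEN`/
#' `SVTYPE` INFO keys, deletion `SVLEN` negative, one genotype column per
#' accession), or the package's TSV, which round-trips exactly through
#' [read_calls()].
#'
#' @param candidates candidate table from [make_candidates()].
#' @param path output file.
#' @param format one of `"tsv"`, `"bed"`, `"vcf_like"`.
#' @param accessions accession names for VCF-like genotype columns; defaults
#'   to the union of supporting accessions.
#' @export
write_calls <- function(candidates, path, format = c("tsv", "bed", "vcf_like"),
                        accessions = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    data.table::fwrite(candidates, path, sep = "\t")
    return(invisible(path))
  }
  if (format == "bed") {
    if (nrow(candidates) == 0L) {
      writeLines("#chrom\tstart\tend\tname\tscore\tstrand", path)
      return(invisible(path))
    }
    bed <- data.frame(candidates$chrom, candidates$start, candidates$end,
                      paste0(candidates$sv_type, ":", candidates$support),
                      candidates$support, ".")
    con <- file(path, "w")
    writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    return(invisible(path))
  }
  if (is.null(accessions)) {
    accessions <- sort(unique(unlist(strsplit(candidates$accessions, ","))))
  }
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2-like",
               "##INFO=<ID=SVTYPE>", "##INFO=<ID=END>", "##INFO=<ID=SVLEN>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", accessions), collapse = "\t")), con)
  for (i in seq_len(nrow(candidates))) {
    x <- candidates[i, ]
    svlen <- if (x$sv_type == "deletion") -x$size else x$size
    carriers <- strsplit(x$accessions, ",")[[1]]
    gt <- ifelse(accessions %in% carriers, "1", "0")
    writeLines(paste(c(x$chrom, x$start + 1L, x$id, "N", paste0("<", toupper(
      substr(x$sv_type, 1, 3)), ">"), ".", "PASS",
      sprintf("SVTYPE=%s;END=%d;SVLEN=%d", x$sv_type, x$end, svlen),
      "GT", gt), collapse = "\t"), con)
  }
  close(con)
  invisible(path)
}

#' Read back a TSV call file written by [write_calls()]
#' @param path TSV call file.
#' @return the candidate table.
#' @export
read_calls <- function(path) {
  data.table::fread(path, sep = "\t")
}
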