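## Discordant read-pair classification, pooled two-dimensional
## single-linkage clustering and SV candidate construction.

#' Classify read pairs as normal, low quality, or discordant
#'
#' A pair is usable only when both mates map with quality >= `min_mapq`.
#' Usable pairs are discordant when they are not in the expected
#' inward-facing (+,-) orientation, when their outer insert span is at
#' least `min_insert`, or when the mates map to different chromosomes.
#' Discordant pairs receive a signature: inward-facing long-insert pairs
#' signal a deletion; (+,+) or (-,-) pairs an inversion; outward-facing
#' (-,+) pairs an eversion; interchromosomal pairs an interchromosomal
#' event.  Eversion and interchromosomal signatures map to transposition
#' candidates downstream.
#'
#' An optional `blacklist` of pair ids is excluded up front (the hook for
#' an external second-opinion re-alignment step).
#'
#' @param pairs a read-pair table.
#' @param min_mapq minimum per-mate mapping quality (default 29).
#' @param min_insert minimum discordant insert span in bp (default 1000).
#' @param blacklist pair ids to drop before classification.
#' @return the table with added columns `class` (`normal`, `low_quality`,
#'   `discordant`) and `signature` (`NA` unless discordant).
#' @export
classify_pairs <- function(pairs, min_mapq = 29, min_insert = 1000,
                           blacklist = NULL) {
  dt <- data.table::as.data.table(pairs)
  if (nrow(dt) == 0L) {
    dt <- empty_pair_table()
    dt[, `:=`(class = character(0), signature = character(0))]
    return(dt[])
  }
  if (!is.null(blacklist)) dt <- dt[!pair_id %in% blacklist]
  low <- dt$mapq_left < min_mapq | dt$mapq_right < min_mapq
  interchrom <- dt$chrom_left != dt$chrom_right
  proper_orient <- dt$strand_left == "+" & dt$strand_right == "-"
  long_insert <- dt$insert_span >= min_insert
  disc <- interchrom | !proper_orient | long_insert
  sig <- rep(NA_character_, nrow(dt))
  sig[proper_orient & long_insert] <- "deletion_signal"
  sig[dt$strand_left == dt$strand_right] <- "inversion_signal"
  sig[dt$strand_left == "-" & dt$strand_right == "+"] <- "eversion_signal"
  sig[interchrom] <- "interchrom_signal"
  dt[, class := ifelse(low, "low_quality",
                       ifelse(disc, "discordant", "normal"))]
  dt[, signature := ifelse(class == "discordant", sig, NA_character_)]
  dt[]
}

#' Pool discordant pairs across accessions
#'
#' Concatenates the discordant pairs of all accessions (labels preserved;
#' pair ids are namespaced by accession) and logs per-accession counts.
#'
#' @param classified one classified table, or a list of per-accession
#'   classified tables from [classify_pairs()].
#' @return the pooled discordant table; per-accession counts attached as
#'   attribute `"counts"`.
#' @export
pool_discordant <- function(classified) {
  if (is.data.frame(classified)) classified <- list(classified)
  pool <- data.table::rbindlist(lapply(classified, function(x) {
    data.table::as.data.table(x)[class == "discordant"]
  }), fill = TRUE)
  counts <- if (nrow(pool)) table(pool$accession) else table(character(0))
  attr(pool, "counts") <- counts
  pool
}

## single-linkage union-find over one signature/chromosome group,
## linking pairs whose left AND right anchor starts are within `window`
link_group <- function(L, R, window) {
  n <- length(L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  o <- order(L)
  for (a in seq_len(n - 1L)) {
    i <- o[a]
    b <- a + 1L
    while (b <= n && L[o[b]] - L[i] <= window) {
      j <- o[b]
      if (abs(R[i] - R[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      b <- b + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster pooled discordant pairs
#'
#' Two-dimensional single-linkage clustering: two pairs (sharing signature
#' and chromosome pair) are linked when both their left anchor starts and
#' their right anchor starts lie within `window` bp of each other; linked
#' components form clusters, and clusters supported by fewer than
#' `min_support` pairs are discarded.  The result is independent of input
#' order.
#'
#' @param pool pooled discordant table from [pool_discordant()].
#' @param window maximum anchor-start separation in bp (default 225).
#' @param min_support minimum pairs per retained cluster (default 3).
#' @return the pool restricted to clustered pairs, with a `cluster_id`
#'   column.
#' @export
cluster_pairs <- function(pool, window = 225, min_support = 3) {
  if (window <= 0 || min_support < 1) {
    stop("window must be > 0 and min_support >= 1")
  }
  dt <- data.table::as.data.table(pool)
  if (nrow(dt) == 0L) {
    dt[, cluster_id := character(0)]
    return(dt)
  }
  data.table::setorder(dt, signature, chrom_left, chrom_right,
                       left_start, right_start, pair_id)
  dt[, grp := .GRP, by = .(signature, chrom_left, chrom_right)]
  dt[, comp := link_group(left_start, right_start, window), by = grp]
  dt[, cluster_id := paste0("c", grp, "_", comp)]
  dt[, n_sup := .N, by = cluster_id]
  res <- dt[n_sup >= min_support]
  res[, c("grp", "comp", "n_sup") := NULL]
  res[]
}

#' Build SV candidates from clusters
#'
#' Maps each cluster's signature to an SV class (deletion, inversion, or
#' transposition for eversion/interchromosomal signatures) and derives the
#' predicted interval.  For deletions the predicted interval runs from the
#' maximum left-anchor end to the minimum right-anchor start (the inner
#' edges of the two anchor groups); clusters whose inner edges cross
#' (non-positive size) are rejected.
#'
#' @param clusters output of [cluster_pairs()].
#' @return a candidate `data.table`: `id`, `sv_type`, `chrom`,
#'   `left_lo/left_hi`, `right_lo/right_hi` (anchor intervals), `start`,
#'   `end`, `size`, `support`, `accessions`, `pair_ids`.
#' @export
make_candidates <- function(clusters) {
  dt <- data.table::as.data.table(clusters)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(
      id = character(), sv_type = character(), chrom = character(),
      left_lo = integer(), left_hi = integer(), right_lo = integer(),
      right_hi = integer(), start = integer(), end = integer(),
      size = integer(), support = integer(), accessions = character(),
      pair_ids = character()))
  }
  if (any(is.na(dt$signature))) stop("cluster contains non-discordant pairs")
  if (nrow(unique(dt[, .(cluster_id, signature)])) !=
      length(unique(dt$cluster_id))) {
    stop("inconsistent signatures within a cluster")
  }
  cand <- dt[, .(
    sv_type = data.table::fcase(
      signature[1] == "deletion_signal", "deletion",
      signature[1] == "inversion_signal", "inversion",
      default = "transposition"),
    chrom = chrom_left[1],
    left_lo = min(left_start), left_hi = max(left_end),
    right_lo = min(right_start), right_hi = max(right_end),
    start = max(left_end), end = min(right_start),
    support = .N,
    accessions = paste(sort(unique(accession)), collapse = ","),
    pair_ids = paste(pair_id, collapse = ",")
  ), by = cluster_id]
  cand[, size := end - start]
  cand <- cand[sv_type != "deletion" | size > 0]
  data.table::setorder(cand, chrom, start)
  cand[, id := sprintf("sv%05d", .I)]
  cand[, cluster_id := NULL]
  data.table::setcolorder(cand, c("id", "sv_type", "chrom", "left_lo",
                                  "left_hi", "right_lo", "right_hi",
                                  "start", "end", "size", "support",
                                  "accessions", "pair_ids"))
  cand[]
}

#' Discordant caller front end
#'
#' Classify, pool, cluster and build candidates in one call.
#'
#' @param pairs read-pair table (all accessions).
#' @param min_mapq,min_insert see [classify_pairs()].
#' @param window,min_support see [cluster_pairs()].
#' @param blacklist see [classify_pairs()].
#' @return list with `candidates`, `pool` and per-accession discordant
#'   `counts`.
#' @export
call_svs <- function(pairs, min_mapq = 29, min_insert = 1000,
                     window = 225, min_support = 3, blacklist = NULL) {
  cls <- classify_pairs(pairs, min_mapq = min_mapq,
                        min_insert = min_insert, blacklist = blacklist)
  pool <- pool_discordant(cls)
  clusters <- cluster_pairs(pool, window = window,
                            min_support = min_support)
  list(candidates = make_candidates(clusters), pool = pool,
       counts = attr(pool, "counts"))
}
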