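# Domain containers and plain-text I/O.
#
# A marker track is a data.frame (class "marker_track") with one row per
# array marker: chrom, pos (1-based bp), logratio (log2 total intensity vs
# a diploid reference, median-centered upstream), baf (B-allele frequency,
# NA for non-polymorphic copy-number probes) and is_snp. Segments and
# calls are ordinary data.frames; all coordinates are 1-based inclusive
# except in BED export.

#' Construct and validate a marker track
#'
#' @param chrom chromosome labels.
#' @param pos 1-based bp positions, strictly increasing within chromosome
#'   (unsorted input is sorted with a warning).
#' @param logratio log2 intensity ratios; rows with non-finite values are
#'   dropped with a message.
#' @param baf B-allele frequencies in `[0, 1]`, `NA` for non-SNP probes.
#' @return a `marker_track` data.frame with columns `chrom`, `pos`,
#'   `logratio`, `baf`, `is_snp` and attribute `n_dropped`.
#' @export
marker_track <- function(chrom, pos, logratio, baf = NULL) {
  n <- length(pos)
  if (is.null(baf)) baf <- rep(NA_real_, n)
  stopifnot(length(chrom) == n, length(logratio) == n, length(baf) == n)
  keep <- is.finite(logratio)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("dropped ", n_dropped, " marker(s) with non-finite Log-ratio")
  x <- data.frame(chrom = as.character(chrom)[keep], pos = as.integer(pos)[keep],
                  logratio = as.numeric(logratio)[keep],
                  baf = as.numeric(baf)[keep], stringsAsFactors = FALSE)
  if (any(x$baf < 0 | x$baf > 1, na.rm = TRUE))
    stop("BAF values must lie in [0, 1]")
  x$is_snp <- !is.na(x$baf)
  o <- order(match(x$chrom, unique(x$chrom)), x$pos)
  if (is.unsorted(o)) {
    warning("markers were not position-sorted; sorting")
    x <- x[o, , drop = FALSE]
  }
  if (any(unlist(tapply(x$pos, x$chrom, function(p) diff(p) <= 0))))
    stop("positions must be strictly increasing within each chromosome")
  rownames(x) <- NULL
  attr(x, "n_dropped") <- n_dropped
  class(x) <- c("marker_track", "data.frame")
  x
}

#' Read a marker table
#'
#' Reads a tab-delimited file with header columns `chrom`, `pos`,
#' `logratio` and optionally `baf` (alternative capitalizations accepted).
#' Rows with non-finite Log-ratio are dropped and counted; a missing `baf`
#' column yields a track with `is_snp` all `FALSE`, on which allelic
#' imbalance cannot later be computed.
#'
#' @param path file path.
#' @return a `marker_track`; attribute `n_dropped` holds the dropped-row
#'   count.
#' @export
read_marker_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  names(x) <- tolower(names(x))
  for (col in c("chrom", "pos", "logratio"))
    if (!col %in% names(x))
      stop("marker table is missing mandatory column '", col, "'")
  marker_track(x$chrom, x$pos, x$logratio,
               if ("baf" %in% names(x)) x$baf else NULL)
}

#' Write a marker table
#'
#' Tab-delimited counterpart of [read_marker_table()].
#'
#' @param track a `marker_track`.
#' @param path output path.
#' @export
write_marker_table <- function(track, path) {
  stopifnot(inherits(track, "marker_track"))
  utils::write.table(track[, c("chrom", "pos", "logratio", "baf")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# Empty segment-table skeleton; downstream modules fill the columns in.
empty_segments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n_markers = integer(0), n_snps = integer(0),
             mean_lr = numeric(0), d_het = numeric(0), d_hom = numeric(0),
             ai_ratio = numeric(0), stringsAsFactors = FALSE)
}

# Validate segment ordering/overlap within chromosomes.
check_segments <- function(segments) {
  for (chr in unique(segments$chrom)) {
    s <- segments[segments$chrom == chr, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on chromosome ", chr)
    if (any(s$end < s$start)) stop("segment end before start on ", chr)
  }
  invisible(TRUE)
}

#' Read a segment or call table
#'
#' @param path tab-delimited file with at least `chrom`, `start`, `end`,
#'   `n_markers`, `mean_lr`.
#' @return a data.frame, validated for ordering and overlap.
#' @export
read_segment_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (col in c("chrom", "start", "end", "n_markers", "mean_lr"))
    if (!col %in% names(x))
      stop("segment table is missing mandatory column '", col, "'")
  check_segments(x)
  x
}

#' Write allele-specific copy number calls
#'
#' `format = "tsv"` writes all columns with 1-based inclusive coordinates.
#' `format = "bed"` writes BED4 (0-based half-open) with the name field
#' `cn{cn}m{minor_cn}` (`m.` when the minor copy number is undefined).
#'
#' @param calls a call table from [call_segments()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_calls <- function(calls, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  check_segments(calls)
  if (format == "tsv") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = calls$chrom,
                      start = calls$start - 1L,
                      end = calls$end,
                      name = paste0("cn", calls$cn, "m",
                                    ifelse(is.na(calls$minor_cn), ".",
                                           calls$minor_cn)))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Scatter-table export for Log-ratio vs allelic-imbalance plots
#'
#' One row per segment with the two plot coordinates, the marker count
#' (point-size weight) and a highlight flag: the sample-wide cloud is
#' drawn grey with one chromosome highlighted in color.
#'
#' @param segments annotated segment table.
#' @param highlight_chrom optional chromosome to flag.
#' @return data.frame with `chrom`, `mean_lr`, `ai_ratio`, `n_markers`,
#'   `highlight`.
#' @export
write_scatter_table <- function(segments, highlight_chrom = NULL) {
  data.frame(chrom = segments$chrom,
             mean_lr = segments$mean_lr,
             ai_ratio = segments$ai_ratio,
             n_markers = segments$n_markers,
             highlight = if (is.null(highlight_chrom)) FALSE
                         else segments$chrom == highlight_chrom,
             stringsAsFactors = FALSE)
}
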