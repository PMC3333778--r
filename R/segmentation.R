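# Changepoint segmentation of marker tracks.
#
# A penalized recursive binary segmentation on the Log-ratio channel,
# optionally unioned with breakpoints from the same search on mirrored
# (and clipped) BAF of SNP markers so that copy-neutral LOH boundaries --
# invisible in Log-ratio -- are still found. The split criterion is the
# reduction in residual sum of squares against a BIC-style threshold
# `alpha * sigma^2 * log(n)`, with sigma estimated robustly from
# first differences. Deterministic given (track, params).

#' Segmentation parameters
#'
#' @param min_markers minimum markers per segment (and minimum distance
#'   between accepted breakpoints).
#' @param alpha penalty multiplier of the BIC-style split threshold;
#'   larger values give fewer, longer segments.
#' @param use_baf_breakpoints also search the mirrored-BAF channel of SNP
#'   markers and union its breakpoints (needed to delimit copy-neutral
#'   LOH).
#' @param baf_clip mirrored BAF deviations are clipped at this value
#'   before the changepoint search; homozygous SNPs (deviation ~0.5) carry
#'   no imbalance signal, and clipping them to a constant sharpens the
#'   heterozygous-SNP signal.
#' @param split_min,split_max marker-count bounds for
#'   [split_short_segments()].
#' @return a `seg_params` list.
#' @export
seg_params <- function(min_markers = 100, alpha = 2.0,
                       use_baf_breakpoints = TRUE, baf_clip = 0.3,
                       split_min = 200, split_max = 400) {
  stopifnot(min_markers >= 1, alpha > 0, split_min > 0,
            split_min <= split_max)
  list(min_markers = as.integer(min_markers), alpha = alpha,
       use_baf_breakpoints = use_baf_breakpoints, baf_clip = baf_clip,
       split_min = as.integer(split_min), split_max = as.integer(split_max))
}

# Recursive binary segmentation of a numeric series.
# Returns breakpoints as the last index of each left-hand piece.
binseg <- function(x, thresh, min_seg) {
  n <- length(x)
  bps <- integer(0)
  if (n < 2L * min_seg) return(bps)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- iv[1L]; r <- iv[2L]
    m <- r - l + 1L
    if (m < 2L * min_seg) next
    xi <- x[l:r]
    cs <- cumsum(xi)
    tot <- cs[m]
    k <- seq.int(min_seg, m - min_seg)
    gain <- cs[k]^2 / k + (tot - cs[k])^2 / (m - k) - tot^2 / m
    kbest <- k[which.max(gain)]
    if (gain[kbest - min_seg + 1L] > thresh) {
      bp <- l + kbest - 1L
      bps <- c(bps, bp)
      stack[[length(stack) + 1L]] <- c(l, bp)
      stack[[length(stack) + 1L]] <- c(bp + 1L, r)
    }
  }
  sort(bps)
}

# Marker-level noise SD from successive differences: sqrt(E[diff^2]/2).
# Captures the full short-range variance (including the het/hom genotype
# mixture on the BAF channel); sparse true jumps inflate it negligibly.
diff_sd <- function(x) {
  if (length(x) < 3L) return(0)
  sqrt(mean(diff(x)^2) / 2)
}

# Merge breakpoints closer than min_seg (e.g. the same boundary found in
# both channels) to the rounded median of each close group, then drop any
# too close to the ends.
merge_breakpoints <- function(bps, n, min_seg) {
  bps <- sort(unique(bps))
  if (length(bps) == 0L) return(integer(0))
  grp <- cumsum(c(1L, as.integer(diff(bps) >= min_seg)))
  merged <- as.integer(round(tapply(bps, grp, stats::median)))
  merged[merged >= min_seg & merged <= n - min_seg]
}

# Segment statistics for one chromosome given breakpoints.
segments_from_breaks <- function(track_chr, bps) {
  n <- nrow(track_chr)
  starts <- c(1L, bps + 1L)
  ends <- c(bps, n)
  out <- empty_segments()
  for (j in seq_along(starts)) {
    i <- starts[j]:ends[j]
    out[j, "chrom"] <- track_chr$chrom[1L]
    out[j, "start"] <- track_chr$pos[starts[j]]
    out[j, "end"] <- track_chr$pos[ends[j]]
    out[j, "n_markers"] <- length(i)
    out[j, "n_snps"] <- sum(track_chr$is_snp[i])
    out[j, "mean_lr"] <- mean(track_chr$logratio[i])
    out[j, c("d_het", "d_hom", "ai_ratio")] <- NA_real_
  }
  out
}

#' Segment a marker track into constant-copy-number pieces
#'
#' Partitions each chromosome by penalized binary segmentation of the
#' Log-ratio, unioned (by default) with breakpoints found on the mirrored
#' BAF of SNP markers. Segment statistics are filled in except the
#' allelic imbalance ratio, which [annotate_ai()] computes downstream.
#'
#' @param track a `marker_track`.
#' @param params a [seg_params()] list.
#' @return a segment table (one partition per chromosome, ordered).
#' @export
segment_track <- function(track, params = seg_params()) {
  stopifnot(inherits(track, "marker_track"))
  out <- empty_segments()
  for (chr in unique(track$chrom)) {
    tc <- track[track$chrom == chr, , drop = FALSE]
    n <- nrow(tc)
    if (n < params$min_markers) {
      warning("chromosome ", chr, " has fewer than ", params$min_markers,
              " markers; kept as a single segment")
      out <- rbind(out, segments_from_breaks(tc, integer(0)))
      next
    }
    s_lr <- diff_sd(tc$logratio)
    thr_lr <- params$alpha * s_lr^2 * log(n)
    bps <- binseg(tc$logratio, thr_lr, params$min_markers)
    if (params$use_baf_breakpoints) {
      snp <- which(tc$is_snp & !is.na(tc$baf))
      if (length(snp) >= 2L * params$min_markers) {
        y <- pmin(fold_baf(tc$baf[snp]), params$baf_clip)
        s_b <- diff_sd(y)
        thr_b <- params$alpha * s_b^2 * log(length(y))
        # min piece in SNP units, scaled by SNP density
        min_snp <- max(2L, as.integer(round(
          params$min_markers * length(snp) / n)))
        bps_b <- binseg(y, thr_b, min_snp)
        bps <- c(bps, snp[bps_b])
      }
    }
    bps <- merge_breakpoints(bps, n, params$min_markers)
    out <- rbind(out, segments_from_breaks(tc, bps))
  }
  rownames(out) <- NULL
  check_segments(out)
  out
}

#' Piece sizes for the short-segment splitter
#'
#' For a parent of `n` markers, the number of pieces k is chosen from
#' `ceiling(n/split_max) .. floor(n/split_min)` so that the mean piece
#' size is closest to the middle of the band (300 markers by default),
#' ties going to the smaller k (longer pieces, more stable allelic
#' imbalance). Sizes are as equal as possible; every size falls within
#' `[split_min, split_max]` whenever `n >= split_min`.
#'
#' @param n parent marker count.
#' @param split_min,split_max marker-count band for the pieces.
#' @return integer vector of piece sizes summing to `n`; `n` itself when
#'   `n < split_min`.
#' @export
split_sizes <- function(n, split_min = 200, split_max = 400) {
  if (split_min > split_max) stop("split_min must not exceed split_max")
  n <- as.integer(n)
  if (n < split_min) return(n)
  ks <- seq.int(ceiling(n / split_max), floor(n / split_min))
  target <- (split_min + split_max) / 2
  k <- ks[which.min(abs(n / ks - target))]  # ties -> smaller k (ks ascending)
  base <- n %/% k
  extra <- n %% k
  as.integer(c(rep(base + 1L, extra), rep(base, k - extra)))
}

#' Split long segments into short pieces for fine-scale scatter plots
#'
#' Re-partitions each segment into contiguous pieces of `split_min` to
#' `split_max` markers (statistics recomputed from member markers), the
#' representation used to resolve double-minute-like amplifications whose
#' copy number varies from cell to cell. Segments shorter than
#' `split_min` are kept unchanged and flagged `short`.
#'
#' @param segments a segment table.
#' @param track the `marker_track` the segments were built from.
#' @param split_min,split_max marker-count band for the pieces.
#' @return a segment table of pieces with an extra logical column `short`.
#' @export
split_short_segments <- function(segments, track, split_min = 200,
                                 split_max = 400) {
  stopifnot(inherits(track, "marker_track"))
  if (split_min > split_max) stop("split_min must not exceed split_max")
  out <- NULL
  for (i in seq_len(nrow(segments))) {
    idx <- which(track$chrom == segments$chrom[i] &
                   track$pos >= segments$start[i] &
                   track$pos <= segments$end[i])
    sizes <- split_sizes(length(idx), split_min, split_max)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    tc <- track[idx, , drop = FALSE]
    pieces <- segments_from_breaks(tc, utils::head(ends, -1L))
    pieces$short <- length(idx) < split_min
    out <- rbind(out, pieces)
  }
  rownames(out) <- NULL
  out
}
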