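# Allelic imbalance ratio: two-means clustering of mirrored BAF.
#
# Within a genomic segment, the B-allele frequencies of its SNPs form two
# groups: heterozygous SNPs near 0.5 (displaced outward by any allelic
# imbalance of the tumor) and homozygous SNPs near 0 and 1. Folding BAF
# about 0.5 makes germline phase irrelevant, and a two-means clustering of
# the folded values yields an inner center (heterozygous SNPs, d_het) and
# an outer center (homozygous SNPs, d_hom). Their ratio d_het/d_hom is the
# allelic imbalance ratio: ~0.1 for a balanced variant under typical array
# noise, approaching 1 for LOH in a pure tumor.

#' Fold B-allele frequencies about 0.5
#'
#' Returns the mirrored deviation `|baf - 0.5|`, the distance of each SNP
#' from equal A/B signal. Folding removes germline phase, so heterozygous
#' SNPs need not be identified in advance.
#'
#' @param baf numeric vector of B-allele frequencies in `[0, 1]`.
#' @return numeric vector of deviations in `[0, 0.5]`.
#' @examples
#' fold_baf(c(0, 0.35, 0.5, 0.65, 1))
#' @export
fold_baf <- function(baf) {
  if (length(baf) == 0L) return(numeric(0))
  if (any(baf < 0 | baf > 1, na.rm = TRUE))
    stop("BAF values must lie in [0, 1]")
  abs(baf - 0.5)
}

#' Two-means clustering of folded BAF deviations
#'
#' Splits 1-D folded deviations into an inner (heterozygous) and an outer
#' (homozygous) cluster by minimizing the within-cluster sum of squares
#' over all threshold partitions of the sorted values -- the global optimum
#' of 2-means in one dimension, found deterministically. When the values
#' are degenerate (all equal, e.g. noiseless LOH) the two centers collapse
#' onto the common value.
#'
#' @param dev numeric vector of folded deviations in `[0, 0.5]`
#'   (see [fold_baf()]).
#' @param min_snps minimum number of values required; below this the
#'   statistic is noise-dominated and `c(NA, NA)` is returned.
#' @param min_frac minimum fraction of the values each cluster must hold.
#'   A genuine heterozygous cluster contains a substantial share of the
#'   SNPs; without this constraint a handful of stray values (e.g.
#'   markers bleeding across an imperfect breakpoint into an LOH segment)
#'   can masquerade as the inner cluster and collapse the ratio.
#' @return named numeric vector `c(d_het = , d_hom = )`, the inner and
#'   outer cluster centers.
#' @examples
#' two_means_fold(c(rep(0.05, 50), rep(0.48, 50)), min_snps = 10)
#' @export
two_means_fold <- function(dev, min_snps = 20, min_frac = 0.05) {
  dev <- dev[is.finite(dev)]
  n <- length(dev)
  if (n < min_snps) return(c(d_het = NA_real_, d_hom = NA_real_))
  x <- sort(dev)
  if (x[n] - x[1L] < .Machine$double.eps^0.5) {
    v <- mean(x)
    return(c(d_het = v, d_hom = v))
  }
  # within-cluster SS of {x[1..k]} and {x[(k+1)..n]} via prefix sums
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  kmin <- max(1L, as.integer(ceiling(min_frac * n)))
  k <- seq.int(kmin, n - kmin)
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kbest <- k[which.min(ss_lo + ss_hi)]
  c(d_het = cs[kbest] / kbest,
    d_hom = (cs[n] - cs[kbest]) / (n - kbest))
}

#' Allelic imbalance ratio
#'
#' Ratio of the inner to the outer cluster center of the folded-BAF
#' two-means clustering, clamped to `[0, 1]`. Collapsed clusters
#' (`d_het == d_hom`, the noiseless-LOH limit) give 1.
#'
#' @param d_het inner cluster center.
#' @param d_hom outer cluster center; must be positive for a defined ratio.
#' @return the ratio in `[0, 1]`, or `NA` if undefined.
#' @export
ai_ratio <- function(d_het, d_hom) {
  if (is.na(d_het) || is.na(d_hom) || d_hom <= 0) return(NA_real_)
  clamp(d_het / d_hom, 0, 1)
}

#' Annotate segments with the allelic imbalance ratio
#'
#' Computes `d_het`, `d_hom` and `ai_ratio` for every segment from the SNP
#' markers it spans. Segments with fewer than `min_snps` SNPs (or none)
#' keep `NA` in all three columns and are excluded from downstream model
#' fitting.
#'
#' @param segments segment table (see [segment_track()]).
#' @param track a `marker_track` supplying per-marker BAF.
#' @param min_snps minimum SNP count per segment (default 20).
#' @return the segment table with `d_het`, `d_hom`, `ai_ratio` filled in.
#' @export
annotate_ai <- function(segments, track, min_snps = 20) {
  stopifnot(inherits(track, "marker_track"))
  for (i in seq_len(nrow(segments))) {
    sel <- track$chrom == segments$chrom[i] &
      track$pos >= segments$start[i] & track$pos <= segments$end[i] &
      track$is_snp & !is.na(track$baf)
    cent <- two_means_fold(fold_baf(track$baf[sel]), min_snps = min_snps)
    d_het <- clamp(cent[["d_het"]], 0, 0.5)
    d_hom <- clamp(cent[["d_hom"]], 0, 0.5)
    segments$d_het[i] <- d_het
    segments$d_hom[i] <- d_hom
    segments$ai_ratio[i] <- ai_ratio(d_het, d_hom)
  }
  segments
}
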