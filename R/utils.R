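# Internal numeric helpers shared across modules.

#' Weighted median
#'
#' Median of `x` with non-negative weights `w`: the smallest value at which
#' the cumulative weight reaches half the total. Used wherever segment
#' statistics are "weighted on their length" (marker count).
#'
#' @param x numeric values.
#' @param w non-negative weights, same length as `x`.
#' @return a single numeric value, or `NA` for empty input.
#' @keywords internal
wmedian <- function(x, w) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  # lower weighted median; interpolate at an exact 0.5 boundary
  i <- which(cw >= 0.5)[1L]
  if (cw[i] == 0.5 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

# Gap-based 1-D clustering: a new cluster starts whenever the sorted
# adjacent gap exceeds `gap`. Returns an integer cluster id per input value
# (in input order), ids increasing with the cluster center.
gap_cluster <- function(x, gap) {
  stopifnot(gap > 0)
  n <- length(x)
  if (n == 0L) return(integer(0))
  o <- order(x)
  id_sorted <- cumsum(c(1L, as.integer(diff(x[o]) > gap)))
  id <- integer(n)
  id[o] <- id_sorted
  id
}

# Weighted exact 1-D two-means: threshold split of sorted values
# minimizing the weighted within-cluster sum of squares. Returns the two
# centers, the split threshold and the weight of each side.
weighted_two_means <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  n <- length(x)
  if (n < 2L) return(list(lo = x[1L], hi = x[1L], w_lo = sum(w), w_hi = 0))
  cw <- cumsum(w); cwx <- cumsum(w * x); cwx2 <- cumsum(w * x^2)
  k <- seq_len(n - 1L)
  ss_lo <- cwx2[k] - cwx[k]^2 / cw[k]
  ss_hi <- (cwx2[n] - cwx2[k]) - (cwx[n] - cwx[k])^2 / (cw[n] - cw[k])
  kb <- which.min(ss_lo + ss_hi)
  list(lo = cwx[kb] / cw[kb],
       hi = (cwx[n] - cwx[kb]) / (cw[n] - cw[kb]),
       w_lo = cw[kb], w_hi = cw[n] - cw[kb],
       lo_idx = o[seq_len(kb)], hi_idx = o[(kb + 1L):n])
}

# E|X| for X ~ N(mu, sd): mean of the folded normal distribution.
# Closed form used by the simulator's expected allelic-imbalance oracle.
folded_normal_mean <- function(mu, sd) {
  if (sd <= 0) return(abs(mu))
  sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * stats::pnorm(-mu / sd))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Chromosome labels treated as autosomes: anything not X/Y (with or
# without a "chr" prefix).
is_autosome <- function(chrom) {
  !(sub("^chr", "", as.character(chrom)) %in% c("X", "Y", "x", "y"))
}
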