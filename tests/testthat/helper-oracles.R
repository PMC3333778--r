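# Independent oracles and small fixture builders used across tests.

# Brute-force 1-D two-means: try every threshold partition of the sorted
# values (subject to the same minimum cluster mass as the implementation)
# and return the centers minimizing the within-cluster sum of squares,
# computed naively with mean() and sum of squared residuals.
naive_two_means <- function(x, min_frac = 0.05) {
  x <- sort(x)
  n <- length(x)
  kmin <- max(1L, as.integer(ceiling(min_frac * n)))
  best <- Inf
  centers <- c(NA_real_, NA_real_)
  for (k in kmin:(n - kmin)) {
    lo <- x[1:k]; hi <- x[(k + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best - 1e-12) {
      best <- wss
      centers <- c(mean(lo), mean(hi))
    }
  }
  centers
}

# Closed-form mean of |N(mu, sd)| (folded normal), written independently
# of the package's internal helper.
fold_mean <- function(mu, sd) {
  sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) + mu * (1 - 2 * pnorm(-mu / sd))
}

# Expected rung Log-ratio for a simulated sample, including the
# background-signal floor and the median-centering shift. The centering
# subtracts the median of the noisy per-marker Log-ratio, i.e. the median
# of a Gaussian mixture over the region states, found by root-solving the
# mixture CDF.
expected_rung_lr <- function(truth, c) {
  f <- truth$tumor_fraction
  psi <- truth$avg_tumor_ploidy
  bs <- truth$background_signal
  reg <- truth$regions
  c_eff <- reg$clone_fraction * reg$c +
    (1 - reg$clone_fraction) * truth$background[1]
  mu <- function(cc) log2((f * cc + 2 * (1 - f) + bs) /
                            (f * psi + 2 * (1 - f)))
  n <- round((reg$end - reg$start + 1) / truth$marker_spacing)
  w <- n / sum(n)
  sd <- truth$noise$sd_lr
  mus <- mu(c_eff)
  shift <- uniroot(function(x) sum(w * pnorm((x - mus) / sd)) - 0.5,
                   range(mus) + c(-1, 1))$root
  mu(c) - shift
}

# Small hand-built segment table for caller unit tests.
toy_segments <- function(lr, ai, n_markers, chrom = "chr1") {
  k <- length(lr)
  end <- cumsum(n_markers) * 1000
  start <- c(1, head(end, -1) + 1)
  data.frame(chrom = chrom, start = start, end = end,
             n_markers = n_markers, n_snps = n_markers,
             mean_lr = lr, d_het = NA_real_, d_hom = NA_real_,
             ai_ratio = ai, stringsAsFactors = FALSE)
}
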