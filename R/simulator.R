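# Synthetic tumor-signal simulator with ground truth.
#
# Emulates the dilution-series benchmark design: a tumor of known
# karyotype (regions of total copy number c and minor copy number m,
# optionally subclonal) mixed with normal diploid cells at tumor cell
# fraction f, measured on a SNP-array-like marker grid with Gaussian
# noise. Because a fixed amount of DNA (not a fixed number of cells) is
# hybridized and intensities are median-centered, the Log-ratio of copy
# number c in a tumor of average ploidy psi is
#   log2( (f*c + 2*(1-f)) / (f*psi + 2*(1-f)) ),
# and at a germline-heterozygous SNP carrying b tumor copies of allele B
# the B-allele frequency is
#   (f*b + (1-f)) / (f*c + 2*(1-f)).

#' Expected Log-ratio of a copy number state
#'
#' @param c total tumor copy number (>= 0).
#' @param f tumor cell fraction in (0, 1].
#' @param psi average tumor ploidy (> 0); median-centering normalizes
#'   total intensity to the ploidy-weighted sample mean.
#' @return expected log2 ratio.
#' @export
expected_logratio <- function(c, f, psi) {
  stopifnot(all(c >= 0), all(f > 0 & f <= 1))
  if (any(psi <= 0)) stop("average ploidy must be positive")
  log2((f * c + 2 * (1 - f)) / (f * psi + 2 * (1 - f)))
}

#' Expected B-allele frequency at a germline-heterozygous SNP
#'
#' @inheritParams expected_logratio
#' @param m minor copy number, `0 <= m <= floor(c/2)`.
#' @param b_on_minor does the B allele sit on the minor-copy homolog?
#' @return expected BAF in `[0, 1]`; defined as 0.5 (no signal) when the
#'   total DNA content at the locus is zero.
#' @export
expected_baf <- function(c, m, f, b_on_minor = TRUE) {
  stopifnot(all(c >= 0), all(m >= 0), all(m <= floor(c / 2)),
            all(f > 0 & f <= 1))
  b <- ifelse(b_on_minor, m, c - m)
  den <- f * c + 2 * (1 - f)
  ifelse(den == 0, 0.5, (f * b + (1 - f)) / den)
}

#' Tumor DNA fraction corresponding to a tumor cell fraction
#'
#' With aneuploid tumor cells, mixing by cell count and by DNA mass
#' differ: a cell fraction f of ploidy-psi tumor cells contributes a DNA
#' fraction `f*psi / (f*psi + 2*(1-f))`. This is the conversion used when
#' a dilution series targets cell fractions by mixing extracted DNA.
#'
#' @param f tumor cell fraction in `[0, 1]`.
#' @param psi average tumor ploidy (> 0).
#' @return tumor DNA fraction in `[0, 1]`.
#' @seealso [cell_fraction_from_dna_fraction()] for the exact inverse.
#' @export
dna_fraction_from_cell_fraction <- function(f, psi) {
  stopifnot(all(f >= 0 & f <= 1), all(psi > 0))
  f * psi / (f * psi + 2 * (1 - f))
}

#' @rdname dna_fraction_from_cell_fraction
#' @param d tumor DNA fraction in `[0, 1]`.
#' @export
cell_fraction_from_dna_fraction <- function(d, psi) {
  stopifnot(all(d >= 0 & d <= 1), all(psi > 0))
  2 * d / (psi * (1 - d) + 2 * d)
}

#' Construct a simulation truth profile
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive bp), `c` (total copy number), `m` (minor copy number) and
#'   optionally `clone_fraction` in (0, 1] (fraction of tumor cells
#'   carrying the state; the remainder keeps the background state `c0`,
#'   `m0`, default cn2m1). Regions must tile each chromosome without
#'   overlap.
#' @param tumor_fraction tumor cell fraction f in (0, 1].
#' @param noise named list or vector with `sd_lr`, `sd_baf_het`,
#'   `sd_baf_hom` (Gaussian marker noise SDs).
#' @param het_rate germline heterozygosity rate among SNPs.
#' @param marker_spacing bp between adjacent markers (uniform density).
#' @param background `c(c0, m0)` state of the non-aberrant cell fraction.
#' @param background_signal residual intensity (in diploid-DNA units)
#'   added to the total-signal numerator when simulating, so that
#'   homozygously deleted regions in a pure tumor produce a deep but
#'   finite Log-ratio, as array background fluorescence does.
#' @return a `truth_profile` list; `avg_tumor_ploidy` is recomputed as the
#'   length-weighted mean of the (clone-mixed) region copy numbers.
#' @export
truth_profile <- function(regions, tumor_fraction,
                          noise = c(sd_lr = 0.20, sd_baf_het = 0.06,
                                    sd_baf_hom = 0.03),
                          het_rate = 1 / 3, marker_spacing = 1000,
                          background = c(2, 1), background_signal = 0.05) {
  stopifnot(is.data.frame(regions),
            all(c("chrom", "start", "end", "c", "m") %in% names(regions)))
  if (!"clone_fraction" %in% names(regions)) regions$clone_fraction <- 1
  stopifnot(tumor_fraction > 0, tumor_fraction <= 1,
            all(regions$clone_fraction > 0 & regions$clone_fraction <= 1),
            all(regions$m <= floor(regions$c / 2)), all(regions$m >= 0))
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (r$start[1] != 1 ||
        any(r$start[-1] != r$end[-nrow(r)] + 1))
      stop("regions must tile chromosome ", chr, " without gaps/overlap")
  }
  len <- regions$end - regions$start + 1
  c_eff <- regions$clone_fraction * regions$c +
    (1 - regions$clone_fraction) * background[1]
  psi <- sum(len * c_eff) / sum(len)
  structure(list(regions = regions, tumor_fraction = tumor_fraction,
                 noise = as.list(noise), het_rate = het_rate,
                 marker_spacing = marker_spacing, background = background,
                 background_signal = background_signal,
                 avg_tumor_ploidy = psi),
            class = "truth_profile")
}

#' Simulate a marker track from a truth profile
#'
#' Markers are laid down at uniform spacing; each is a SNP whose germline
#' genotype is heterozygous with probability `het_rate` (B on either
#' homolog with probability 1/2). Subclonal regions mix the aberrant and
#' background states by `clone_fraction`, giving non-integer effective
#' copy numbers. Log-ratio gets additive Gaussian noise and a final
#' median-centering; heterozygous BAF gets Gaussian noise clamped to
#' `[0, 1]`; homozygous BAF is 0 or 1 displaced inward by `|N(0, sd)|`.
#'
#' @param profile a [truth_profile()].
#' @param seed integer RNG seed (bit-identical output per seed).
#' @return list with `track` (a `marker_track`) and `truth` (the profile,
#'   with a per-region marker-index table in `$regions`).
#' @export
simulate_sample <- function(profile, seed = 1) {
  stopifnot(inherits(profile, "truth_profile"))
  set.seed(as.integer(seed))
  f <- profile$tumor_fraction
  psi <- profile$avg_tumor_ploidy
  ns <- profile$noise
  bg <- profile$background
  reg <- profile$regions
  reg <- reg[order(match(reg$chrom, unique(reg$chrom)), reg$start), ,
             drop = FALSE]
  chroms <- character(0); pos <- integer(0)
  lr <- numeric(0); baf <- numeric(0)
  reg$first_marker <- NA_integer_; reg$n_markers <- NA_integer_
  total <- 0L
  for (i in seq_len(nrow(reg))) {
    p <- seq.int(reg$start[i], reg$end[i], by = profile$marker_spacing)
    n <- length(p)
    cf <- reg$clone_fraction[i]
    c_eff <- cf * reg$c[i] + (1 - cf) * bg[1]
    m_eff <- cf * reg$m[i] + (1 - cf) * bg[2]
    mu_lr <- log2((f * c_eff + 2 * (1 - f) + profile$background_signal) /
                    (f * psi + 2 * (1 - f)))
    het <- stats::runif(n) < profile$het_rate
    b_minor <- stats::runif(n) < 0.5
    mu_baf <- expected_baf_eff(c_eff, m_eff, f, b_minor)
    lr_i <- mu_lr + stats::rnorm(n, 0, ns$sd_lr)
    baf_i <- ifelse(het,
                    clamp(mu_baf + stats::rnorm(n, 0, ns$sd_baf_het), 0, 1),
                    abs((stats::runif(n) < 0.5) -
                          abs(stats::rnorm(n, 0, ns$sd_baf_hom))))
    chroms <- c(chroms, rep(as.character(reg$chrom[i]), n))
    pos <- c(pos, p); lr <- c(lr, lr_i); baf <- c(baf, clamp(baf_i, 0, 1))
    reg$first_marker[i] <- total + 1L
    reg$n_markers[i] <- n
    total <- total + n
  }
  lr <- lr - stats::median(lr)  # median-centering of total intensities
  track <- marker_track(chroms, pos, lr, baf)
  truth <- profile
  truth$regions <- reg
  truth$seed <- as.integer(seed)
  list(track = track, truth = truth)
}

# expected_baf for possibly non-integer effective (c, m): linear mixing of
# signal is already captured because expected_baf is a ratio of linear
# DNA amounts; bypass the integer-m guard.
expected_baf_eff <- function(c, m, f, b_on_minor = TRUE) {
  b <- ifelse(b_on_minor, m, c - m)
  den <- f * c + 2 * (1 - f)
  ifelse(den == 0, 0.5, (f * b + (1 - f)) / den)
}

#' Expected allelic imbalance ratio under the mixture model
#'
#' Asymptotic value of the two-means allelic imbalance ratio for a segment
#' in state (c, m) at tumor fraction f under the simulator's noise model,
#' computed from one large noiseless-breakpoint Monte Carlo draw (fixed
#' internal seed) of folded BAF values passed through the same clustering
#' definition. Used as the coordinate oracle for ladder recovery checks.
#'
#' @inheritParams expected_baf
#' @param noise noise list as in [truth_profile()].
#' @param het_rate germline heterozygosity rate.
#' @param n number of SNPs drawn.
#' @return list with `d_het`, `d_hom`, `ai`.
#' @export
expected_ai <- function(c, m, f,
                        noise = list(sd_baf_het = 0.06, sd_baf_hom = 0.03),
                        het_rate = 1 / 3, n = 2e5) {
  rs <- local({ set.seed(424242L)
    het <- stats::runif(n) < het_rate
    b_minor <- stats::runif(n) < 0.5
    mu <- expected_baf_eff(c, m, f, b_minor)
    baf <- ifelse(het,
                  clamp(mu + stats::rnorm(n, 0, noise$sd_baf_het), 0, 1),
                  abs((stats::runif(n) < 0.5) -
                        abs(stats::rnorm(n, 0, noise$sd_baf_hom))))
    two_means_fold(fold_baf(baf))
  })
  list(d_het = rs[["d_het"]], d_hom = rs[["d_hom"]],
       ai = ai_ratio(rs[["d_het"]], rs[["d_hom"]]))
}

#' Simulate a dilution series
#'
#' One sample per tumor cell fraction, sharing the karyotype but with
#' independent noise and germline draws (seed derived as `seed + index`).
#'
#' @param base_profile a [truth_profile()]; its `tumor_fraction` is
#'   overridden per sample.
#' @param fractions tumor cell fractions, each in (0, 1].
#' @param seed base RNG seed.
#' @return list of [simulate_sample()] results, named by fraction.
#' @export
make_dilution_series <- function(base_profile,
                                 fractions = c(1.0, 0.7, 0.5, 0.3),
                                 seed = 1) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  out <- vector("list", length(fractions))
  names(out) <- paste0("f", fractions)
  for (i in seq_along(fractions)) {
    p <- base_profile
    p$tumor_fraction <- fractions[i]
    out[[i]] <- simulate_sample(p, seed = as.integer(seed) + i - 1L)
  }
  out
}
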