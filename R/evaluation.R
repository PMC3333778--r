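# Sensitivity/specificity protocol against simulated truth, and the
# end-to-end pipeline wrapper.
#
# A truth aberration counts as detected when more than half of its marker
# span is covered by calls with exactly the right (total, minor) copy
# number; breakpoint placement is deliberately ignored. Specificity is
# the fraction of the truly unaltered (cn2m1) marker span reported as
# cn2m1. Spans are measured in markers: marker count is what calls and
# truth share, and at the simulator's uniform density it coincides with
# genomic length.

# Per-marker (cn, minor_cn) from a call table.
states_at_markers <- function(calls, track) {
  cn <- rep(NA_integer_, nrow(track))
  m <- rep(NA_integer_, nrow(track))
  for (chr in unique(track$chrom)) {
    i <- which(track$chrom == chr)
    cc <- calls[calls$chrom == chr, , drop = FALSE]
    if (nrow(cc) == 0L) next
    cc <- cc[order(cc$start), , drop = FALSE]
    j <- findInterval(track$pos[i], cc$start)
    ok <- j > 0L & track$pos[i] <= cc$end[pmax(j, 1L)]
    cn[i[ok]] <- cc$cn[j[ok]]
    m[i[ok]] <- if ("minor_cn" %in% names(cc)) cc$minor_cn[j[ok]] else NA
  }
  list(cn = cn, m = m)
}

#' Sensitivity of allele-specific copy number calls
#'
#' Fraction of truth aberrations (regions differing from the cn2m1
#' background) that are "mostly correct": the exact (total, minor) copy
#' number is called over more than half of the region's marker span.
#' Also reported for the LOH subset (minor copy number 0).
#'
#' @param calls call table from [call_segments()].
#' @param truth_regions truth region table (`chrom`, `start`, `end`, `c`,
#'   `m`) as in a [truth_profile()].
#' @param track the `marker_track` both refer to.
#' @param total_only relaxed debugging mode matching total copy number
#'   only.
#' @return list with `sensitivity_all` and `sensitivity_loh` (percent)
#'   and the per-region `verdicts` data.frame.
#' @export
sensitivity <- function(calls, truth_regions, track, total_only = FALSE) {
  ab <- truth_regions[!(truth_regions$c == 2 & truth_regions$m == 1), ,
                      drop = FALSE]
  if (nrow(ab) == 0L) stop("truth contains no aberrant regions")
  st <- states_at_markers(calls, track)
  frac <- numeric(nrow(ab))
  for (i in seq_len(nrow(ab))) {
    k <- which(track$chrom == ab$chrom[i] & track$pos >= ab$start[i] &
                 track$pos <= ab$end[i])
    hit <- st$cn[k] == ab$c[i]
    if (!total_only) hit <- hit & st$m[k] == ab$m[i]
    hit[is.na(hit)] <- FALSE  # uncovered or minor-undetermined markers
    frac[i] <- if (length(hit)) mean(hit) else 0
  }
  verdicts <- cbind(ab, correct_fraction = frac, detected = frac > 0.5)
  list(sensitivity_all = 100 * mean(verdicts$detected),
       sensitivity_loh = if (any(ab$m == 0))
         100 * mean(verdicts$detected[ab$m == 0]) else NA_real_,
       verdicts = verdicts)
}

#' Specificity of allele-specific copy number calls
#'
#' Percentage of the truly unaltered genome (clonal cn2m1 truth regions,
#' in markers) correctly reported as cn2m1.
#'
#' @inheritParams sensitivity
#' @return specificity in percent, or `NA` if the truth has no unaltered
#'   span.
#' @export
specificity <- function(calls, truth_regions, track) {
  cf <- if ("clone_fraction" %in% names(truth_regions))
    truth_regions$clone_fraction else 1
  un <- truth_regions[truth_regions$c == 2 & truth_regions$m == 1 &
                        cf == 1, , drop = FALSE]
  if (nrow(un) == 0L) {
    message("truth contains no unaltered span; specificity undefined")
    return(NA_real_)
  }
  st <- states_at_markers(calls, track)
  tn <- 0L; total <- 0L
  for (i in seq_len(nrow(un))) {
    k <- which(track$chrom == un$chrom[i] & track$pos >= un$start[i] &
                 track$pos <= un$end[i])
    total <- total + length(k)
    tn <- tn + sum(st$cn[k] == 2L & st$m[k] == 1L, na.rm = TRUE)
  }
  100 * tn / total
}

# Evaluation report for one sample.
eval_report <- function(calls, truth, track, total_only = FALSE) {
  sens <- sensitivity(calls, truth$regions, track, total_only)
  data.frame(sens_all = sens$sensitivity_all,
             sens_loh = sens$sensitivity_loh,
             spec = specificity(calls, truth$regions, track))
}

#' Run the full analysis pipeline
#'
#' Segment, annotate allelic imbalance, build the ladder, call, flag
#' heterogeneity, estimate average ploidy, and (when truth is available)
#' evaluate. Input is either an existing `marker_track` (optionally with
#' a pre-computed segment table, bypassing internal segmentation) or the
#' name of a simulation preset.
#'
#' @param track a `marker_track`, or `NULL` to simulate.
#' @param truth optional `truth_profile` matching `track`.
#' @param preset simulation preset name (see [preset_profile()]) when
#'   `track` is `NULL`.
#' @param tumor_fraction tumor cell fraction for the simulation.
#' @param seed RNG seed for the simulation.
#' @param segments optional pre-computed segment table.
#' @param sparams segmentation parameters ([seg_params()]).
#' @param cparams calling parameters ([call_params()]).
#' @param manual optional [manual_seed()] for the ladder.
#' @return list with `track`, `truth`, `segments`, `ladder`, `calls`,
#'   `avg_ploidy`, `report` (NULL without truth) and `seed`.
#' @export
run_pipeline <- function(track = NULL, truth = NULL, preset = NULL,
                         tumor_fraction = 1.0, seed = 1, segments = NULL,
                         sparams = seg_params(), cparams = call_params(),
                         manual = NULL) {
  if (is.null(track)) {
    if (is.null(preset)) stop("supply a marker track or a preset name")
    sim <- simulate_sample(preset_profile(preset, tumor_fraction), seed)
    track <- sim$track
    truth <- sim$truth
  }
  if (is.null(segments)) segments <- segment_track(track, sparams)
  segments <- annotate_ai(segments, track)
  ladder <- build_ladder(segments, seed = manual, params = cparams)
  calls <- call_segments(segments, ladder, cparams)
  calls <- flag_heterogeneous(calls, ladder, cparams)
  report <- if (!is.null(truth)) eval_report(calls, truth, track)
  list(track = track, truth = truth, segments = segments,
       ladder = ladder, calls = calls,
       avg_ploidy = estimate_average_ploidy(calls), report = report,
       seed = seed)
}
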