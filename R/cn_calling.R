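# Iterative allele-specific copy number calling.
#
# Each segment is a point in the (mean Log-ratio, allelic imbalance
# ratio) plane. Rather than fitting one global model of purity and
# ploidy, the caller builds a sample-specific *ladder* of expected
# coordinates for each (total, minor) copy number state, working
# iteratively from low to high copy number and adjusting every
# expectation toward observed segment clusters:
#
#   1. locate the Log-ratio of copy number 2 among the lowest-intensity
#      long autosomal segment clusters (the one with the lower allelic
#      imbalance: unaltered regions are the most balanced);
#   2. read off the allelic imbalance of cn1, cn2m1 and cn2m0 near that
#      Log-ratio;
#   3. (if 1 or 2 fails) accept a manual seed from a scatter-plot
#      interpretation;
#   4. for each higher copy number, predict its Log-ratio from the
#      spacing of the lower rungs (spacing shrinks slowly, factor `rho`)
#      and snap to the length-weighted median of matching segments;
#   5. predict each minor-copy-number level by extending the fixed-m
#      diagonals seen at lower copy numbers (slope decaying by `rho_ai`),
#      again snapping to matching observations.
#
# Segments are then assigned the nearest ladder point in a scaled
# distance, LOH is minor copy 0, and segments stranded between rungs on
# sufficient length are flagged as heterogeneous (subclonal).

#' Calling parameters
#'
#' Numeric knobs of the ladder caller, defaulted for SNP6-like noise.
#'
#' @param long_min minimum markers for a segment to count as "long" in
#'   the copy-number-2 search.
#' @param gap_lr Log-ratio gap opening a new 1-D cluster.
#' @param ambiguity_ai minimum allelic-imbalance separation between the
#'   two candidate low clusters; below it the cn2 search fails.
#' @param lr_tol Log-ratio half-window around a rung when collecting the
#'   low-copy allelic-imbalance levels.
#' @param gap_ai allelic-imbalance gap separating the balanced and LOH
#'   modes at copy number 2.
#' @param rho decay of the inter-copy Log-ratio spacing per copy.
#' @param rho_ai decay of the fixed-m diagonal slope per copy.
#' @param match_frac matching tolerance, as a fraction of the local
#'   spacing, for snapping predictions to observed segments.
#' @param step_lo,step_hi acceptance window (multiples of the predicted
#'   spacing) for the next observed rung above the current one; the
#'   window is wide because the true spacing shrinks faster than `rho` in
#'   near-pure samples.
#' @param min_cluster_markers minimum summed marker count before a
#'   segment cluster may define or update a ladder rung; smaller clusters
#'   (including short subclonal regions) must not attract the ladder.
#' @param fallback_step initial inter-copy spacing when no cluster below
#'   cn2 exists.
#' @param max_cn highest total copy number on the ladder.
#' @param s_ai_floor floor of the allelic-imbalance distance scale.
#' @param het_frac heterogeneity threshold: fraction of the local
#'   inter-rung distance a segment must exceed to be flagged.
#' @param long_het minimum markers for a heterogeneity flag.
#' @return a `call_params` list.
#' @export
call_params <- function(long_min = 2000, gap_lr = 0.1, ambiguity_ai = 0.05,
                        lr_tol = 0.08, gap_ai = 0.12, rho = 0.9,
                        rho_ai = 0.9, match_frac = 0.25, step_lo = 0.5,
                        step_hi = 1.4, min_cluster_markers = 1000,
                        fallback_step = 0.25, max_cn = 8,
                        s_ai_floor = 0.05, het_frac = 0.3, long_het = 500) {
  stopifnot(max_cn >= 2, rho > 0, rho_ai > 0, step_lo < step_hi)
  as.list(environment())
}

#' Manual ladder seed
#'
#' An analyst-supplied initial interpretation of the scatter plot, used
#' when the automatic cn2 search fails (e.g. genome-wide LOH). Any subset
#' of the allelic-imbalance values may be given.
#'
#' @param lr_cn2 Log-ratio of copy number 2.
#' @param ai_cn2m1,ai_cn2m0,ai_cn1 allelic imbalance ratios of the three
#'   low-copy anchor states, each in `[0, 1]` or `NULL`.
#' @return a `manual_seed` list.
#' @export
manual_seed <- function(lr_cn2, ai_cn2m1 = NULL, ai_cn2m0 = NULL,
                        ai_cn1 = NULL) {
  vals <- c(ai_cn2m1, ai_cn2m0, ai_cn1)
  stopifnot(is.finite(lr_cn2), all(vals >= 0 & vals <= 1))
  structure(list(lr_cn2 = lr_cn2, ai_cn2m1 = ai_cn2m1,
                 ai_cn2m0 = ai_cn2m0, ai_cn1 = ai_cn1),
            class = "manual_seed")
}

# Segments usable for model fitting: autosomal with a defined allelic
# imbalance ratio (sex chromosomes are excluded by default: the Log-ratio
# baseline of X/Y depends on sex, not on aberration).
fit_segments <- function(segments, include_sex = FALSE) {
  keep <- !is.na(segments$ai_ratio)
  if (!include_sex) keep <- keep & is_autosome(segments$chrom)
  segments[keep, , drop = FALSE]
}

# Length-weighted 1-D LR clusters of fitting segments.
lr_clusters <- function(segs, gap_lr) {
  id <- gap_cluster(segs$mean_lr, gap_lr)
  do.call(rbind, lapply(split(seq_len(nrow(segs)), id), function(i) {
    data.frame(lr = wmedian(segs$mean_lr[i], segs$n_markers[i]),
               ai = wmedian(segs$ai_ratio[i], segs$n_markers[i]),
               weight = sum(segs$n_markers[i]))
  }))
}

#' Estimate the Log-ratio of copy number 2
#'
#' Groups long autosomal segments into Log-ratio clusters and, among the
#' two lowest, selects the one with the lower length-weighted median
#' allelic imbalance: unaltered (cn2m1) regions are more balanced than
#' deletions or LOH at similar intensity. Fails with a condition of class
#' `"cn2_estimation_error"` when no long segment qualifies or the two
#' candidates are not separable, in which case a [manual_seed()] must be
#' supplied.
#'
#' @param segments annotated segment table (see [annotate_ai()]).
#' @param params a [call_params()] list.
#' @return list with `lr_cn2` and the candidate `clusters` table.
#' @export
estimate_cn2_logratio <- function(segments, params = call_params()) {
  segs <- fit_segments(segments)
  segs <- segs[segs$n_markers >= params$long_min, , drop = FALSE]
  if (nrow(segs) == 0L)
    stop(structure(class = c("cn2_estimation_error", "error", "condition"),
                   list(message = "no long autosomal segments with a defined allelic imbalance ratio; supply a manual_seed",
                        call = sys.call())))
  cl <- lr_clusters(segs, params$gap_lr)
  cl <- cl[order(cl$lr), , drop = FALSE]
  cand <- utils::head(cl, 2L)
  if (nrow(cand) == 2L &&
      abs(cand$ai[1L] - cand$ai[2L]) < params$ambiguity_ai)
    stop(structure(class = c("cn2_estimation_error", "error", "condition"),
                   list(message = "lowest Log-ratio clusters have indistinguishable allelic imbalance; supply a manual_seed",
                        call = sys.call())))
  pick <- cand[which.min(cand$ai), , drop = FALSE]
  list(lr_cn2 = pick$lr, clusters = cl)
}

#' Allelic imbalance levels of the low copy number states
#'
#' Reads the allelic imbalance ratios of cn2m1 (balanced mode), cn2m0
#' (LOH mode at the same Log-ratio) and cn1 (one spacing below) from the
#' annotated segments; missing states get documented extrapolations
#' (cn2m0: cn2m1 + 0.45 capped at 1; cn1: midway between the two).
#'
#' @param segments annotated segment table.
#' @param lr_cn2 Log-ratio of copy number 2.
#' @param lr_step0 initial inter-copy Log-ratio spacing.
#' @param params a [call_params()] list.
#' @return list with `ai_cn2m1`, `ai_cn2m0`, `ai_cn1` and logical
#'   `observed` flags.
#' @export
estimate_low_cn_ai <- function(segments, lr_cn2, lr_step0,
                               params = call_params()) {
  segs <- fit_segments(segments)
  near2 <- segs[abs(segs$mean_lr - lr_cn2) <= params$lr_tol, ,
                drop = FALSE]
  if (nrow(near2) == 0L)
    stop("no segments near the copy-number-2 Log-ratio")
  # bimodality split of the AI values (weighted two-means): the modes are
  # cn2m1 (balanced) and, when present, cn2m0 (copy-neutral LOH)
  tm <- weighted_two_means(near2$ai_ratio, near2$n_markers)
  obs_m0 <- (tm$hi - tm$lo) > params$gap_ai &&
    tm$w_hi >= params$min_cluster_markers
  if (obs_m0) {
    ai_cn2m1 <- wmedian(near2$ai_ratio[tm$lo_idx],
                        near2$n_markers[tm$lo_idx])
    ai_cn2m0 <- wmedian(near2$ai_ratio[tm$hi_idx],
                        near2$n_markers[tm$hi_idx])
  } else {
    ai_cn2m1 <- wmedian(near2$ai_ratio, near2$n_markers)
    ai_cn2m0 <- min(1, ai_cn2m1 + 0.45)
  }
  near1 <- segs[abs(segs$mean_lr - (lr_cn2 - lr_step0)) <= params$lr_tol, ,
                drop = FALSE]
  obs_c1 <- sum(near1$n_markers) >= params$min_cluster_markers
  ai_cn1 <- if (obs_c1) wmedian(near1$ai_ratio, near1$n_markers)
            else (ai_cn2m1 + ai_cn2m0) / 2
  list(ai_cn2m1 = ai_cn2m1, ai_cn2m0 = ai_cn2m0, ai_cn1 = ai_cn1,
       observed = c(cn2m1 = TRUE, cn2m0 = obs_m0, cn1 = obs_c1))
}

#' Build the sample-specific copy number ladder
#'
#' Runs the full iterative procedure: cn2 location (or manual seed),
#' low-copy allelic imbalance levels, then rung-by-rung extension to
#' `max_cn` with observation-matched updates of both coordinates. The
#' result is the grid of expected (Log-ratio, allelic imbalance)
#' coordinates for every state `(c, m)`, `m = 0..floor(c/2)`,
#' `c = 0..max_cn`, each tagged `observed` or `extrapolated`.
#'
#' @param segments annotated segment table.
#' @param seed optional [manual_seed()].
#' @param max_cn highest total copy number (overrides `params$max_cn`).
#' @param params a [call_params()] list.
#' @return a `cn_ladder` data.frame with columns `cn`, `m`, `lr`, `ai`,
#'   `provenance`; attributes `lr_cn2`, `steps` (inter-copy spacings) and
#'   `ai_gap2` (the cn2 LOH-balanced gap used as a fallback scale).
#' @export
build_ladder <- function(segments, seed = NULL, max_cn = NULL,
                         params = call_params()) {
  if (is.null(max_cn)) max_cn <- params$max_cn
  if (max_cn < 2) stop("max_cn must be at least 2")
  segs <- fit_segments(segments)
  if (nrow(segs) == 0L) stop("no segments with a defined allelic imbalance ratio")

  lr_cn2 <- if (!is.null(seed)) seed$lr_cn2
            else estimate_cn2_logratio(segments, params)$lr_cn2

  cl <- lr_clusters(segs, params$gap_lr)
  anchors <- cl[cl$weight >= params$min_cluster_markers, , drop = FALSE]
  anchors <- anchors[order(anchors$lr), , drop = FALSE]

  # initial spacing: gap from cn2 down to the nearest anchor cluster below
  below <- anchors[anchors$lr < lr_cn2 - params$gap_lr / 2, , drop = FALSE]
  if (nrow(below) > 0L) {
    lr1 <- below$lr[nrow(below)]
    step0 <- lr_cn2 - lr1
    obs1 <- TRUE
  } else {
    step0 <- params$fallback_step
    lr1 <- lr_cn2 - step0
    obs1 <- FALSE
  }

  low <- estimate_low_cn_ai(segments, lr_cn2, step0, params)
  if (!is.null(seed)) {
    if (!is.null(seed$ai_cn2m1)) low$ai_cn2m1 <- seed$ai_cn2m1
    if (!is.null(seed$ai_cn2m0)) low$ai_cn2m0 <- seed$ai_cn2m0
    if (!is.null(seed$ai_cn1)) low$ai_cn1 <- seed$ai_cn1
  }
  ai_bal <- low$ai_cn2m1

  lr_of <- c(`0` = lr1 - step0 / params$rho, `1` = lr1, `2` = lr_cn2)
  steps <- c(`1` = step0 / params$rho, `2` = step0)
  prov_lr <- c(`0` = "extrapolated", `1` = if (obs1) "observed" else "extrapolated",
               `2` = "observed")

  ladder <- data.frame(
    cn = c(0L, 1L, 2L, 2L), m = c(0L, 0L, 1L, 0L),
    lr = c(lr_of[["0"]], lr_of[["1"]], lr_cn2, lr_cn2),
    ai = c(ai_bal, low$ai_cn1, low$ai_cn2m1, low$ai_cn2m0),
    provenance = c("extrapolated",
                   if (low$observed[["cn1"]]) "observed" else "extrapolated",
                   "observed",
                   if (low$observed[["cn2m0"]]) "observed" else "extrapolated"),
    stringsAsFactors = FALSE)

  get_ai <- function(cc, mm) {
    i <- which(ladder$cn == cc & ladder$m == mm)
    if (length(i)) ladder$ai[i] else NA_real_
  }

  for (cc in 3:max_cn) {
    prev <- lr_of[[as.character(cc - 1L)]]
    pred_step <- params$rho * steps[[as.character(cc - 1L)]]
    win <- anchors[anchors$lr > prev + params$step_lo * pred_step &
                     anchors$lr < prev + params$step_hi * pred_step, ,
                   drop = FALSE]
    if (nrow(win) > 0L) {
      lr_c <- win$lr[1L]  # lowest cluster in the window is the next rung
      prov <- "observed"
    } else {
      lr_c <- prev + pred_step
      prov <- "extrapolated"
    }
    lr_of[[as.character(cc)]] <- lr_c
    steps[[as.character(cc)]] <- lr_c - prev
    prov_lr[[as.character(cc)]] <- prov

    # predict the AI level of every m at this copy number
    ms <- 0:(cc %/% 2L)
    ai_pred <- numeric(length(ms))
    prov_ai <- rep("extrapolated", length(ms))
    lr_m1 <- lr_of[[as.character(cc - 1L)]]
    lr_m2 <- lr_of[[as.character(cc - 2L)]]
    # m = 0 diagonal always has two lower points
    sl0 <- (get_ai(cc - 1L, 0L) - get_ai(cc - 2L, 0L)) /
      max(lr_m1 - lr_m2, 1e-6)
    ai_c0 <- clamp(get_ai(cc - 1L, 0L) +
                     params$rho_ai * sl0 * (lr_c - lr_m1), 0, 1)
    for (j in seq_along(ms)) {
      mm <- ms[j]
      if (mm == 0L) {
        ai_pred[j] <- ai_c0
      } else if (2L * mm == cc) {
        ai_pred[j] <- ai_bal  # balanced state: same level at every c
      } else if (!is.na(get_ai(cc - 1L, mm)) && !is.na(get_ai(cc - 2L, mm))) {
        sl <- (get_ai(cc - 1L, mm) - get_ai(cc - 2L, mm)) /
          max(lr_m1 - lr_m2, 1e-6)
        ai_pred[j] <- clamp(get_ai(cc - 1L, mm) +
                              params$rho_ai * sl * (lr_c - lr_m1), 0, 1)
      } else {
        # first appearance of this m beyond the balanced state (c = 2m+1):
        # interpolate by the imbalance fraction (c-2m)/c, which is
        # independent of purity, between the balanced level and m = 0
        ai_pred[j] <- clamp(ai_bal + (cc - 2 * mm) / cc * (ai_c0 - ai_bal),
                            0, 1)
      }
    }

    # observation-matched update of the AI levels at this rung
    memb <- segs[abs(segs$mean_lr - lr_c) <=
                   params$match_frac * abs(steps[[as.character(cc)]]), ,
                 drop = FALSE]
    if (nrow(memb) > 0L && length(ms) > 0L) {
      assign_lvl <- vapply(memb$ai_ratio, function(a)
        which.min(abs(a - ai_pred)), integer(1))
      for (j in seq_along(ms)) {
        sel <- assign_lvl == j
        gapj <- if (length(ai_pred) > 1L)
          min(abs(ai_pred[j] - ai_pred[-j])) else 0.2
        tol <- max(params$s_ai_floor, params$match_frac * gapj)
        sel <- sel & abs(memb$ai_ratio - ai_pred[j]) <= tol
        if (sum(memb$n_markers[sel]) >= params$min_cluster_markers) {
          ai_pred[j] <- wmedian(memb$ai_ratio[sel], memb$n_markers[sel])
          prov_ai[j] <- "observed"
        }
      }
    }
    # enforce strict decrease of AI in m
    for (j in rev(seq_along(ms))[-1L]) {
      if (ai_pred[j] <= ai_pred[j + 1L])
        ai_pred[j] <- ai_pred[j + 1L] + 1e-4
    }

    prov_c <- ifelse(prov_ai == "observed" & prov == "observed",
                     "observed", "extrapolated")
    ladder <- rbind(ladder, data.frame(
      cn = cc, m = ms, lr = lr_c, ai = ai_pred, provenance = prov_c,
      stringsAsFactors = FALSE))
  }

  ladder <- ladder[order(ladder$cn, ladder$m), , drop = FALSE]
  rownames(ladder) <- NULL
  attr(ladder, "lr_cn2") <- lr_cn2
  attr(ladder, "steps") <- unlist(steps)
  attr(ladder, "ai_gap2") <- max(low$ai_cn2m0 - low$ai_cn2m1, 0.1)
  class(ladder) <- c("cn_ladder", "data.frame")
  ladder
}

# Distance scales per copy number: s_lr is the local inter-copy spacing,
# s_ai the mean gap between adjacent m levels at that copy number (cn2's
# LOH-balanced gap where a rung has a single level), both floored.
ladder_scales <- function(ladder, s_ai_floor = 0.05) {
  steps <- attr(ladder, "steps")
  cns <- sort(unique(ladder$cn))
  s_lr <- vapply(cns, function(cc) {
    lo <- steps[as.character(cc)]
    hi <- steps[as.character(cc + 1L)]
    max(mean(c(lo, hi), na.rm = TRUE), 0.05)
  }, numeric(1))
  s_ai <- vapply(cns, function(cc) {
    a <- sort(ladder$ai[ladder$cn == cc])
    if (length(a) > 1L) max(mean(diff(a)), s_ai_floor)
    else max(attr(ladder, "ai_gap2") / 2, s_ai_floor)
  }, numeric(1))
  data.frame(cn = cns, s_lr = s_lr, s_ai = s_ai)
}

# Scaled squared distances from one (lr, ai) point to all ladder entries.
ladder_distances <- function(ladder, scales, lr, ai) {
  s <- scales[match(ladder$cn, scales$cn), ]
  d2 <- ((lr - ladder$lr) / s$s_lr)^2
  if (!is.na(ai)) d2 <- d2 + ((ai - ladder$ai) / s$s_ai)^2
  d2
}

#' Call total and minor copy number for every segment
#'
#' Assigns each segment the ladder state minimizing the scaled squared
#' distance in the (Log-ratio, allelic imbalance) plane; the scales are
#' the local inter-copy spacing and the local gap between minor-copy
#' levels, so "one rung off" costs about the same in either coordinate.
#' Exact ties go to the larger minor copy number (the less drastic
#' interpretation, avoiding spurious LOH). Segments without a defined
#' allelic imbalance ratio are placed on Log-ratio alone with `minor_cn`
#' and `loh` left `NA`.
#'
#' @param segments annotated segment table.
#' @param ladder a `cn_ladder` from [build_ladder()].
#' @param params a [call_params()] list.
#' @return the segment table with `cn`, `minor_cn`, `loh`,
#'   `heterogeneous` (filled by [flag_heterogeneous()]) and
#'   `call_distance` columns.
#' @export
call_segments <- function(segments, ladder, params = call_params()) {
  if (!inherits(ladder, "cn_ladder") || nrow(ladder) == 0L)
    stop("ladder is empty or not a cn_ladder")
  scales <- ladder_scales(ladder, params$s_ai_floor)
  calls <- segments
  calls$cn <- NA_integer_; calls$minor_cn <- NA_integer_
  calls$loh <- NA; calls$heterogeneous <- FALSE
  calls$call_distance <- NA_real_
  for (i in seq_len(nrow(calls))) {
    d2 <- ladder_distances(ladder, scales, calls$mean_lr[i],
                           calls$ai_ratio[i])
    if (is.na(calls$ai_ratio[i])) {
      # Log-ratio only: pick the nearest copy number, minor undetermined
      best <- which(d2 <= min(d2) + 1e-12)
      calls$cn[i] <- ladder$cn[best[1L]]
      calls$call_distance[i] <- sqrt(min(d2))
      next
    }
    best <- which(d2 <= min(d2) + 1e-12)
    if (length(best) > 1L) best <- best[which.max(ladder$m[best])]
    calls$cn[i] <- ladder$cn[best]
    calls$minor_cn[i] <- ladder$m[best]
    calls$loh[i] <- ladder$m[best] == 0L && ladder$cn[best] >= 1L
    calls$call_distance[i] <- sqrt(d2[best])
  }
  calls
}

#' Flag segments stranded between ladder rungs as heterogeneous
#'
#' A segment whose scaled distance to its nearest ladder state exceeds
#' `het_frac` of the distance between its two nearest states -- and which
#' is long enough for that displacement to be signal rather than noise --
#' indicates a copy number present in only part of the tumor cell
#' population (subclonal, or cell-to-cell variable as in double minutes).
#'
#' @param calls call table from [call_segments()].
#' @param ladder the `cn_ladder` used for calling.
#' @param params a [call_params()] list (`het_frac`, `long_het`).
#' @return the call table with `heterogeneous` updated.
#' @export
flag_heterogeneous <- function(calls, ladder, params = call_params()) {
  scales <- ladder_scales(ladder, params$s_ai_floor)
  for (i in seq_len(nrow(calls))) {
    if (is.na(calls$ai_ratio[i]) || calls$n_markers[i] < params$long_het)
      next
    d2 <- ladder_distances(ladder, scales, calls$mean_lr[i],
                           calls$ai_ratio[i])
    o <- order(d2)
    e1 <- o[1L]; e2 <- o[2L]
    s1 <- scales[match(ladder$cn[e1], scales$cn), ]
    gap <- sqrt(((ladder$lr[e1] - ladder$lr[e2]) / s1$s_lr)^2 +
                  ((ladder$ai[e1] - ladder$ai[e2]) / s1$s_ai)^2)
    calls$heterogeneous[i] <- sqrt(d2[e1]) > params$het_frac * gap
  }
  calls
}

#' Average ploidy of the tumor cells
#'
#' Marker-count-weighted mean total copy number over called autosomal
#' segments; the marker count is the proxy for genomic length at uniform
#' marker density.
#'
#' @param calls call table.
#' @return average ploidy; attribute `coverage` gives the fraction of
#'   autosomal markers in called (non-`NA`) segments, with a warning
#'   below 50%.
#' @export
estimate_average_ploidy <- function(calls) {
  auto <- calls[is_autosome(calls$chrom), , drop = FALSE]
  called <- auto[!is.na(auto$cn), , drop = FALSE]
  cov <- sum(called$n_markers) / sum(auto$n_markers)
  if (!is.finite(cov) || cov < 0.5)
    warning("copy number calls cover under half of the autosomal markers")
  psi <- sum(called$n_markers * called$cn) / sum(called$n_markers)
  attr(psi, "coverage") <- cov
  psi
}
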