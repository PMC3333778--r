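test_that("the cn2 Log-ratio is the low-imbalance one of the two lowest clusters", {
  segs <- toy_segments(lr = c(-0.5, -0.02, 0.02, 0.4),
                       ai = c(0.55, 0.12, 0.13, 0.3),
                       n_markers = c(2500, 2500, 2500, 2500))
  est <- estimate_cn2_logratio(segs)
  expect_equal(est$lr_cn2, wmedian(c(-0.02, 0.02), c(2500, 2500)),
               tolerance = 1e-9)

  one <- toy_segments(0.02, 0.1, 2500)
  expect_equal(estimate_cn2_logratio(one)$lr_cn2, 0.02)

  # indistinguishable imbalance of the two candidates -> explicit failure
  amb <- toy_segments(c(-0.4, 0.0), c(0.30, 0.28), c(2500, 2500))
  expect_error(estimate_cn2_logratio(amb), class = "cn2_estimation_error")
  # no long segments at all -> explicit failure
  short <- toy_segments(c(-0.4, 0.0), c(0.5, 0.1), c(500, 500))
  expect_error(estimate_cn2_logratio(short), class = "cn2_estimation_error")
})

test_that("low-copy imbalance levels are read off or extrapolated as stated", {
  segs <- toy_segments(lr = c(0.0, 0.01, -0.3),
                       ai = c(0.12, 0.55, 0.35),
                       n_markers = c(3000, 2000, 2000))
  lv <- estimate_low_cn_ai(segs, lr_cn2 = 0, lr_step0 = 0.3)
  expect_equal(lv$ai_cn2m1, 0.12)
  expect_equal(lv$ai_cn2m0, 0.55)
  expect_equal(lv$ai_cn1, 0.35)
  expect_true(all(lv$observed))

  noloh <- toy_segments(c(0.0, -0.3), c(0.12, 0.35), c(3000, 2000))
  lv2 <- estimate_low_cn_ai(noloh, 0, 0.3)
  expect_equal(lv2$ai_cn2m0, 0.57)
  expect_false(lv2$observed[["cn2m0"]])
})

test_that("pure extrapolation follows the decaying-spacing recurrence", {
  # anchors at LR(1) = -0.35, LR(2) = 0; nothing observable above
  segs <- toy_segments(lr = c(-0.35, 0.0, 0.01),
                       ai = c(0.50, 0.10, 0.54),
                       n_markers = c(3000, 3000, 2000))
  lad <- build_ladder(segs, max_cn = 4,
                      params = call_params(long_min = 1000))
  lr3 <- lad$lr[lad$cn == 3][1]
  lr4 <- lad$lr[lad$cn == 4][1]
  expect_equal(lr3, 0.315, tolerance = 0.02)
  expect_equal(lr4 - lr3, 0.9 * (lr3 - 0), tolerance = 1e-9)
  expect_true(all(lad$provenance[lad$cn >= 3] == "extrapolated"))
})

test_that("ladder invariants hold and observed rungs recover simulator truth", {
  for (cfg in list(c(f = 0.7, seed = 2), c(f = 0.3, seed = 6),
                   c(f = 1.0, seed = 3))) {
    sim <- simulate_sample(preset_profile("triploid", cfg[["f"]]),
                           cfg[["seed"]])
    segs <- annotate_ai(segment_track(sim$track), sim$track)
    lad <- build_ladder(segs)
    # monotone geometry
    rung_lr <- tapply(lad$lr, lad$cn, unique)
    expect_true(all(diff(unlist(rung_lr)) > 0))
    for (cc in unique(lad$cn)) {
      a <- lad$ai[lad$cn == cc][order(lad$m[lad$cn == cc])]
      if (length(a) > 1) expect_true(all(diff(a) < 0))
    }
    expect_true(all(lad$m <= lad$cn %/% 2))
    # observed entries sit on the mixture-model expectations
    obs <- lad[lad$provenance == "observed", ]
    for (i in seq_len(nrow(obs))) {
      expect_lt(abs(obs$lr[i] - expected_rung_lr(sim$truth, obs$cn[i])),
                0.05)
      eai <- expected_ai(obs$cn[i], obs$m[i], cfg[["f"]])$ai
      expect_lt(abs(obs$ai[i] - eai), 0.05)
    }
  }
})

test_that("manual seeding overrides a failed automatic start", {
  # genome-wide LOH lookalike: both low clusters highly imbalanced
  segs <- toy_segments(lr = c(-0.3, 0.0, 0.3),
                       ai = c(0.60, 0.62, 0.40),
                       n_markers = c(3000, 3000, 3000))
  expect_error(build_ladder(segs), class = "cn2_estimation_error")
  lad <- build_ladder(segs, seed = manual_seed(0.0, ai_cn2m1 = 0.1,
                                               ai_cn2m0 = 0.62,
                                               ai_cn1 = 0.6))
  expect_equal(attr(lad, "lr_cn2"), 0.0)
  expect_equal(lad$ai[lad$cn == 2 & lad$m == 1], 0.1)
  expect_error(manual_seed(0, ai_cn2m1 = 1.4))
})

test_that("segments are assigned the nearest ladder state, ties to larger minor copy", {
  sim <- simulate_sample(preset_profile("triploid", 0.7), 5)
  segs <- annotate_ai(segment_track(sim$track), sim$track)
  lad <- build_ladder(segs)
  calls <- call_segments(segs, lad)
  # a segment placed exactly on a rung: zero distance, correct label
  probe <- segs[1, ]
  probe$mean_lr <- lad$lr[lad$cn == 2 & lad$m == 0]
  probe$ai_ratio <- lad$ai[lad$cn == 2 & lad$m == 0]
  pc <- call_segments(probe, lad)
  expect_equal(pc$cn, 2L); expect_equal(pc$minor_cn, 0L)
  expect_true(pc$loh)
  expect_equal(pc$call_distance, 0)
  # equidistant in the scaled metric between (3,1) and (3,0): larger m wins
  l31 <- lad[lad$cn == 3 & lad$m == 1, ]; l30 <- lad[lad$cn == 3 & lad$m == 0, ]
  probe$mean_lr <- l31$lr
  probe$ai_ratio <- (l31$ai + l30$ai) / 2
  pc2 <- call_segments(probe, lad)
  expect_equal(pc2$minor_cn, 1L)
  # AI-less segments are placed on Log-ratio alone
  probe$ai_ratio <- NA_real_
  probe$mean_lr <- lad$lr[lad$cn == 4][1]
  pc3 <- call_segments(probe, lad)
  expect_equal(pc3$cn, 4L)
  expect_true(is.na(pc3$minor_cn))
  expect_error(call_segments(segs, data.frame()), "ladder")
  # loh flag is exactly (minor 0, cn >= 1)
  expect_equal(calls$loh, calls$minor_cn == 0 & calls$cn >= 1)
})

test_that("calling is invariant to a global Log-ratio shift", {
  sim <- simulate_sample(preset_profile("diploid", 0.6), 8)
  r1 <- run_pipeline(track = sim$track, truth = sim$truth)
  tr2 <- sim$track
  tr2$logratio <- tr2$logratio + 0.37
  r2 <- run_pipeline(track = tr2, truth = sim$truth)
  expect_equal(r2$calls$cn, r1$calls$cn)
  expect_equal(r2$calls$minor_cn, r1$calls$minor_cn)
  expect_equal(attr(r2$ladder, "lr_cn2") - attr(r1$ladder, "lr_cn2"), 0.37,
               tolerance = 0.02)
})

test_that("segments midway between rungs are flagged heterogeneous, rung-dwellers are not", {
  sim <- simulate_sample(preset_profile("triploid", 0.7), 1)
  segs <- annotate_ai(segment_track(sim$track), sim$track)
  lad <- build_ladder(segs)
  l21 <- lad[lad$cn == 2 & lad$m == 1, ]; l10 <- lad[lad$cn == 1, ]
  probe <- segs[1, ]
  probe$n_markers <- 1000L
  probe$mean_lr <- (l21$lr + l10$lr) / 2
  probe$ai_ratio <- (l21$ai + l10$ai) / 2
  fc <- flag_heterogeneous(call_segments(probe, lad), lad)
  expect_true(fc$heterogeneous)
  probe$mean_lr <- l21$lr; probe$ai_ratio <- l21$ai
  fc2 <- flag_heterogeneous(call_segments(probe, lad), lad)
  expect_false(fc2$heterogeneous)
  probe$mean_lr <- (l21$lr + l10$lr) / 2
  probe$ai_ratio <- (l21$ai + l10$ai) / 2
  probe$n_markers <- 120L  # too short for the flag
  fc3 <- flag_heterogeneous(call_segments(probe, lad), lad)
  expect_false(fc3$heterogeneous)
})

test_that("average ploidy is the marker-weighted mean copy number", {
  calls <- toy_segments(c(0, 0), c(0.1, 0.1), c(5000, 5000))
  calls$cn <- c(2L, 2L); calls$minor_cn <- 1L
  expect_equal(as.numeric(estimate_average_ploidy(calls)), 2)
  calls$cn <- c(2L, 4L)
  expect_equal(as.numeric(estimate_average_ploidy(calls)), 3)
  calls$cn <- c(2L, NA)
  calls$n_markers <- c(4000L, 6000L)  # called span falls under half
  expect_warning(psi <- estimate_average_ploidy(calls), "half")
  expect_equal(as.numeric(psi), 2)
})
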