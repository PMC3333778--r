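# A miniature two-region truth with hand-made calls exercises the
# >50%-of-markers verdict rule without any pipeline involvement.
mini_world <- function() {
  reg <- data.frame(chrom = "chr1",
                    start = c(1, 1e6 + 1, 2e6 + 1),
                    end = c(1e6, 2e6, 3e6),
                    c = c(2, 3, 1), m = c(1, 1, 0))
  profile <- truth_profile(reg, tumor_fraction = 1)
  track <- simulate_sample(profile, 1)$track
  list(reg = reg, track = track)
}

test_that("sensitivity applies the mostly-correct (>50% of markers) rule", {
  w <- mini_world()
  perfect <- data.frame(chrom = "chr1",
                        start = c(1, 1e6 + 1, 2e6 + 1),
                        end = c(1e6, 2e6, 3e6),
                        cn = c(2L, 3L, 1L), minor_cn = c(1L, 1L, 0L))
  s <- sensitivity(perfect, w$reg, w$track)
  expect_equal(s$sensitivity_all, 100)
  expect_equal(s$sensitivity_loh, 100)

  # one aberration 60% correct, the other 40% -> 50%
  part <- data.frame(chrom = "chr1",
                     start = c(1, 1e6 + 1, 1.6e6 + 1, 2e6 + 1, 2.4e6 + 1),
                     end = c(1e6, 1.6e6, 2e6, 2.4e6, 3e6),
                     cn = c(2L, 3L, 2L, 1L, 2L),
                     minor_cn = c(1L, 1L, 1L, 0L, 1L))
  s2 <- sensitivity(part, w$reg, w$track)
  expect_equal(s2$sensitivity_all, 50)
  expect_equal(nrow(s2$verdicts), 2L)

  # correct total but wrong minor copy fails strict mode, passes relaxed
  m_off <- perfect; m_off$minor_cn[2] <- 0L
  expect_equal(sensitivity(m_off, w$reg, w$track)$sensitivity_all, 50)
  expect_equal(sensitivity(m_off, w$reg, w$track,
                           total_only = TRUE)$sensitivity_all, 100)
  expect_error(sensitivity(perfect, w$reg[1, ], w$track), "aberrant")
})

test_that("specificity is the correctly-unaltered share of the cn2m1 span", {
  w <- mini_world()
  allflat <- data.frame(chrom = "chr1", start = 1, end = 3e6,
                        cn = 2L, minor_cn = 1L)
  expect_equal(specificity(allflat, w$reg, w$track), 100)
  expect_equal(sensitivity(allflat, w$reg, w$track)$sensitivity_all, 0)

  part <- data.frame(chrom = "chr1", start = c(1, 9e5 + 1),
                     end = c(9e5, 3e6), cn = c(2L, 3L),
                     minor_cn = c(1L, 1L))
  expect_equal(specificity(part, w$reg, w$track), 90)
  noflat <- w$reg[w$reg$c != 2, ]
  expect_message(sp <- specificity(allflat, noflat, w$track), "unaltered")
  expect_true(is.na(sp))
})

test_that("scores are invariant to fragmentation that preserves the labels", {
  r <- run_pipeline(preset = "diploid", tumor_fraction = 0.7, seed = 2)
  calls <- r$calls
  # split every call in two at its midpoint marker
  frag <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    cc <- calls[i, ]
    mid <- cc$start + ((cc$end - cc$start) %/% 2000) * 1000
    if (mid <= cc$start || mid >= cc$end) return(cc)
    a <- cc; a$end <- mid
    b <- cc; b$start <- mid + 1
    rbind(a, b)
  }))
  s1 <- sensitivity(calls, r$truth$regions, r$track)
  s2 <- sensitivity(frag, r$truth$regions, r$track)
  expect_equal(s2$sensitivity_all, s1$sensitivity_all)
  expect_equal(specificity(frag, r$truth$regions, r$track),
               specificity(calls, r$truth$regions, r$track))
})

test_that("the pipeline is reproducible and honors pre-computed segments", {
  r1 <- run_pipeline(preset = "subclone", tumor_fraction = 0.8, seed = 5)
  r2 <- run_pipeline(preset = "subclone", tumor_fraction = 0.8, seed = 5)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$calls, r2$calls)

  pre <- segment_track(r1$track)
  r3 <- run_pipeline(track = r1$track, truth = r1$truth, segments = pre)
  expect_equal(r3$calls$cn, r1$calls$cn)
  expect_error(run_pipeline(), "preset")
})

test_that("a full dilution series yields one report row per fraction", {
  ser <- make_dilution_series(preset_profile("dilution"), seed = 1)
  rep4 <- do.call(rbind, lapply(ser, function(s)
    run_pipeline(track = s$track, truth = s$truth)$report))
  expect_equal(nrow(rep4), 4L)
  expect_true(all(rep4$spec >= 0 & rep4$spec <= 100))
  expect_true(all(rep4$sens_all >= 0 & rep4$sens_all <= 100))
})
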