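test_that("mixture-model closed forms match hand-computed values", {
  expect_equal(expected_logratio(2, 0.6, 2), 0)
  expect_equal(expected_logratio(4, 1, 2), 1)
  expect_equal(expected_logratio(3, 0.5, 2), log2(2.5 / 2))
  expect_equal(expected_logratio(3, 0.5, 2), 0.32193, tolerance = 1e-4)
  expect_error(expected_logratio(2, 1, 0), "ploidy")

  expect_equal(expected_baf(2, 1, 0.8), 0.5)
  expect_equal(expected_baf(2, 0, 0.3, b_on_minor = TRUE), 0.35)
  expect_equal(expected_baf(3, 1, 1, b_on_minor = TRUE), 1 / 3)
  expect_equal(expected_baf(0, 0, 1), 0.5)  # no DNA: no signal

  expect_equal(dna_fraction_from_cell_fraction(0.4, 2), 0.4)
  expect_equal(dna_fraction_from_cell_fraction(0.5, 3), 0.6)
  expect_equal(dna_fraction_from_cell_fraction(1, 5.2), 1)
  # the published dilution design: 30/50/70% cells of a near-triploid
  # tumor require 42/65/80% tumor DNA
  expect_equal(round(100 * dna_fraction_from_cell_fraction(
    c(0.3, 0.5, 0.7), 3.35)), c(42, 63, 80), tolerance = 2)
})

test_that("Log-ratio rises with copy number; folded BAF with imbalance; DNA fraction inverts", {
  lr <- expected_logratio(0:8, 0.4, 3)
  expect_true(all(diff(lr) > 0))
  dev <- abs(expected_baf(6, c(3, 2, 1, 0), 0.5) - 0.5)
  expect_true(all(diff(dev) > 0))
  f <- seq(0.05, 1, by = 0.05)
  d <- dna_fraction_from_cell_fraction(f, 3.2)
  expect_true(all(diff(d) > 0))
  expect_true(all(abs(cell_fraction_from_dna_fraction(d, 3.2) - f) < 1e-9))
})

test_that("truth profiles validate tiling and recompute average ploidy", {
  reg <- data.frame(chrom = "chr1", start = c(1, 1e6 + 1),
                    end = c(1e6, 3e6), c = c(2, 4), m = c(1, 2))
  p <- truth_profile(reg, 0.5)
  expect_equal(p$avg_tumor_ploidy, (1 * 2 + 2 * 4) / 3)
  bad <- reg; bad$start[2] <- 2e6
  expect_error(truth_profile(bad, 0.5), "tile")
  bad2 <- reg; bad2$m[2] <- 3
  expect_error(truth_profile(bad2, 0.5))
})

test_that("simulation is seeded-deterministic and noiseless signals are exact", {
  p <- preset_profile("diploid", 0.8)
  a <- simulate_sample(p, 9); b <- simulate_sample(p, 9)
  expect_identical(a$track, b$track)
  expect_false(identical(a$track, simulate_sample(p, 10)$track))

  flat <- truth_profile(
    data.frame(chrom = "chr1", start = 1, end = 5e6, c = 2, m = 1),
    tumor_fraction = 1,
    noise = c(sd_lr = 0, sd_baf_het = 0, sd_baf_hom = 0),
    background_signal = 0)
  s <- simulate_sample(flat, 1)
  expect_true(all(s$track$logratio == 0))
  set.seed(1)  # regenerate the germline to identify het SNPs
  het <- runif(nrow(s$track)) < flat$het_rate
  expect_true(all(s$track$baf[het] == 0.5))
  expect_true(all(s$track$baf[!het] %in% c(0, 1)))
})

test_that("the dilution preset carries 35 aberrations, 14 with LOH, near-triploid", {
  p <- preset_profile("dilution", 0.5)
  ab <- p$regions[!(p$regions$c == 2 & p$regions$m == 1), ]
  expect_equal(nrow(ab), 35L)
  expect_equal(sum(ab$m == 0), 14L)
  expect_gt(p$avg_tumor_ploidy, 3)
  expect_lt(p$avg_tumor_ploidy, 3.5)
  expect_equal(preset_profile("diploid")$avg_tumor_ploidy, 2.0)
})

test_that("a dilution series shares the karyotype and shrinks imbalance with f", {
  ser <- make_dilution_series(preset_profile("subclone"), c(1.0, 0.7, 0.3),
                              seed = 3)
  expect_named(ser, c("f1", "f0.7", "f0.3"))
  ai_loh <- vapply(ser, function(s) {
    k <- s$track$pos >= 2500001 & s$track$pos <= 4000000
    ct <- two_means_fold(fold_baf(s$track$baf[k]))
    ai_ratio(ct[["d_het"]], ct[["d_hom"]])
  }, numeric(1))
  expect_true(ai_loh[["f0.3"]] < ai_loh[["f0.7"]])
  expect_true(ai_loh[["f0.7"]] < ai_loh[["f1"]])
  expect_error(make_dilution_series(preset_profile("subclone"), c(0.5, 1.2)),
               "fractions")
})
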