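test_that("confusion_rates reproduces the screening arithmetic", {
  cr <- confusion_rates(std_rad(), std_cohort())
  expect_equal(cr$tp, 0.013140, tolerance = 1e-9)
  expect_equal(cr$fp, 0.078832, tolerance = 1e-9)
  expect_equal(cr$fn, 0.001460, tolerance = 1e-9)
  expect_equal(cr$tn, 0.906568, tolerance = 1e-9)

  cr80 <- confusion_rates(operating_point(0.80, 0.80), std_cohort())
  expect_equal(unlist(cr80[c("tp", "fp", "fn", "tn")]),
               c(tp = 0.011680, fp = 0.197080, fn = 0.002920, tn = 0.788320),
               tolerance = 1e-9)

  # perfect reader at arbitrary prevalence
  perfect <- confusion_rates(operating_point(1, 1), cohort(0.3))
  expect_equal(perfect$tp, 0.3)
  expect_equal(perfect$tn, 0.7)
  expect_identical(perfect$fp, 0)
  expect_identical(perfect$fn, 0)
})

test_that("confusion rates conserve mass and stratify by prevalence", {
  pts <- random_operating_points(50, seed = 11)
  prevs <- c(0, 0.0146, 0.5, 1)
  for (p in prevs) {
    for (i in seq_len(nrow(pts))) {
      cr <- confusion_rates(operating_point(pts$sens[i], pts$spec[i]), cohort(p))
      expect_equal(cr$tp + cr$fp + cr$tn + cr$fn, 1, tolerance = 1e-12)
      expect_equal(cr$tp + cr$fn, p, tolerance = 1e-12)
      expect_equal(cr$fp + cr$tn, 1 - p, tolerance = 1e-12)
    }
  }
})

test_that("out-of-range inputs are rejected with the offending field named", {
  expect_error(operating_point(1.2, 0.9), "sensitivity")
  expect_error(operating_point(0.9, -0.1), "specificity")
  expect_error(cohort(1.5), "prevalence")
  expect_error(cohort(0.5, size = 2.5), "size")
  expect_error(protocol_timing(-1, 776), "t_abbr")
  expect_warning(protocol_timing(800, 776), "t_abbr")
})

test_that("overlap_bounds matches frozen values and the brute-force oracle", {
  coh <- std_cohort()
  rad <- confusion_rates(std_rad(), coh)
  ai <- confusion_rates(std_ai(), coh)
  ov <- overlap_bounds(rad, ai)
  expect_equal(ov$maximum, 0.090512, tolerance = 1e-9)
  expect_equal(ov$minimum, 0.010220, tolerance = 1e-9)

  # AI flags everyone: overlap pinned to the radiologist flag rate
  always <- confusion_rates(operating_point(1, 0), coh)
  ov2 <- overlap_bounds(rad, always)
  expect_equal(ov2$minimum, 0.091972, tolerance = 1e-9)
  expect_equal(ov2$maximum, 0.091972, tolerance = 1e-9)

  # identical readers: tp stratum forced, fp stratum free down to zero
  ov3 <- overlap_bounds(rad, rad)
  expect_equal(ov3$maximum, 0.091972, tolerance = 1e-9)
  expect_equal(ov3$minimum, 0.011680, tolerance = 1e-9)

  # property: agreement with the independent joint-table search
  pts <- random_operating_points(8, seed = 7)
  for (i in seq_len(nrow(pts))) {
    ai_i <- operating_point(pts$sens[i], pts$spec[i])
    got <- overlap_bounds(rad, confusion_rates(ai_i, coh))
    want <- oracle_overlap_bounds(std_rad(), ai_i, 0.0146)
    expect_lt(abs(got$minimum - want$minimum), 3e-4)
    expect_lt(abs(got$maximum - want$maximum), 3e-4)
    expect_lte(got$maximum, min(flag_rate_of(rad), pts$sens[i] * 0.0146 +
                                  (1 - pts$spec[i]) * 0.9854) + 1e-12)
  }
})

test_that("overlap_bounds rejects mismatched prevalences", {
  rad <- confusion_rates(std_rad(), cohort(0.0146))
  ai <- confusion_rates(std_ai(), cohort(0.02))
  expect_error(overlap_bounds(rad, ai), "prevalence mismatch")
})

test_that("rr_adaptive and epd_adaptive reproduce the limit arithmetic", {
  coh <- std_cohort()
  rad <- confusion_rates(std_rad(), coh)
  ai <- confusion_rates(std_ai(), coh)
  ov <- overlap_bounds(rad, ai)

  expect_equal(rr_adaptive(rad, ov$maximum, ov), 0.001460, tolerance = 1e-9)
  expect_equal(rr_adaptive(rad, ov$minimum, ov), 0.081752, tolerance = 1e-9)
  expect_error(rr_adaptive(rad, 0.5, ov), "outside feasible range")

  # lower limit reaches zero when AI sensitivity matches the radiologist's
  ai90 <- confusion_rates(operating_point(0.90, 0.80), coh)
  ov90 <- overlap_bounds(rad, ai90)
  expect_equal(rr_adaptive(rad, ov90$maximum, ov90), 0)

  tm <- std_timing()
  expect_equal(epd_adaptive(ai, 0.001460, tm), 370.4356, tolerance = 1e-6)
  expect_equal(epd_adaptive(ai, 0.081752, tm), 432.742192, tolerance = 1e-6)

  # never-flagging AI with abbreviated-only recall reduces to abbreviated-only
  never <- confusion_rates(operating_point(0, 1), coh)
  rr_abbr <- rr_abbreviated_only(rad)
  expect_equal(epd_adaptive(never, rr_abbr, tm),
               epd_abbreviated_only(rad, tm), tolerance = 1e-9)
})

test_that("baseline strategies match their closed forms", {
  coh <- std_cohort()
  tm <- std_timing()
  rad <- confusion_rates(std_rad(), coh)
  expect_equal(rr_abbreviated_only(rad), 0.091972, tolerance = 1e-9)
  expect_equal(epd_abbreviated_only(rad, tm), 333.370272, tolerance = 1e-6)

  # degenerate baselines
  expect_equal(rr_abbreviated_only(confusion_rates(operating_point(0.5, 1),
                                                   cohort(0))), 0)
  expect_equal(rr_abbreviated_only(confusion_rates(operating_point(1, 0),
                                                   cohort(0.3))), 1)
  none <- confusion_rates(operating_point(0, 1), cohort(0))
  expect_equal(epd_abbreviated_only(none, tm), tm$t_abbr)
  all_fl <- confusion_rates(operating_point(1, 0), cohort(0.5))
  expect_equal(epd_abbreviated_only(all_fl, tm), tm$t_abbr + tm$t_full)

  full <- metrics_full_only(tm)
  expect_identical(full$rr, 0)
  expect_equal(full$epd, 776)
  expect_equal(metrics_full_only(protocol_timing(100, 100))$epd, 100)
})

test_that("adaptive_bounds composes the chain and honours degeneracies", {
  coh <- std_cohort()
  tm <- std_timing()
  ad <- adaptive_bounds(std_rad(), std_ai(), coh, tm)
  expect_equal(unname(ad$rr), c(0.001460, 0.081752), tolerance = 1e-9)
  expect_equal(unname(ad$epd), c(370.4356, 432.742192), tolerance = 1e-6)

  # always-flagging AI degenerates to full-only
  ad_full <- adaptive_bounds(std_rad(), operating_point(1, 0), coh, tm)
  expect_equal(unname(ad_full$rr), c(0, 0))
  expect_equal(unname(ad_full$epd), c(776, 776))

  # never-flagging AI degenerates to abbreviated-only
  ad_abbr <- adaptive_bounds(std_rad(), operating_point(0, 1), coh, tm)
  expect_equal(unname(ad_abbr$rr), rep(0.091972, 2), tolerance = 1e-9)
  expect_equal(unname(ad_abbr$epd), rep(333.370272, 2), tolerance = 1e-6)
})

test_that("RR is enveloped by the baselines; EPD is not", {
  coh <- std_cohort()
  tm <- std_timing()
  rad <- confusion_rates(std_rad(), coh)
  rr_abbr <- rr_abbreviated_only(rad)
  epd_abbr <- epd_abbreviated_only(rad, tm)
  pts <- random_operating_points(100, seed = 42)
  epd_below_abbr <- FALSE
  epd_above_full <- FALSE
  for (i in seq_len(nrow(pts))) {
    ad <- adaptive_bounds(std_rad(),
                          operating_point(pts$sens[i], pts$spec[i]), coh, tm)
    expect_gte(ad$rr[[1]], 0)
    expect_lte(ad$rr[[1]], ad$rr[[2]] + 1e-12)
    expect_lte(ad$rr[[2]], rr_abbr + 1e-12)
    expect_lte(ad$epd[[1]], ad$epd[[2]] + 1e-9)
    if (ad$epd[[1]] < epd_abbr) epd_below_abbr <- TRUE
    if (ad$epd[[2]] > tm$t_full) epd_above_full <- TRUE
  }
  expect_true(epd_below_abbr)
  expect_true(epd_above_full)
})

test_that("limits are monotone in the expected directions", {
  coh <- std_cohort()
  tm <- std_timing()
  se_grid <- seq(0, 1, by = 0.02)
  rr_lo <- rr_hi <- numeric(length(se_grid))
  for (i in seq_along(se_grid)) {
    ad <- adaptive_bounds(std_rad(), operating_point(se_grid[i], 0.80), coh, tm)
    rr_lo[i] <- ad$rr[[1]]
    rr_hi[i] <- ad$rr[[2]]
  }
  expect_true(all(diff(rr_lo) <= 1e-12))
  expect_true(all(diff(rr_hi) <= 1e-12))

  sp_grid <- seq(0.08, 0.92, by = 0.02)
  epd_lo <- epd_hi <- numeric(length(sp_grid))
  for (i in seq_along(sp_grid)) {
    ad <- adaptive_bounds(std_rad(), operating_point(0.80, sp_grid[i]), coh, tm)
    epd_lo[i] <- ad$epd[[1]]
    epd_hi[i] <- ad$epd[[2]]
  }
  expect_true(all(diff(epd_lo) <= 1e-9))
  expect_true(all(diff(epd_hi) <= 1e-9))
})

test_that("degenerate prevalence keeps every operation total", {
  tm <- std_timing()
  for (p in c(0, 1)) {
    ad <- adaptive_bounds(std_rad(), std_ai(), cohort(p), tm)
    expect_true(all(unlist(ad$rr) >= 0 & unlist(ad$rr) <= 1))
    expect_true(all(unlist(ad$epd) > 0))
  }
})
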