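test_that("calibration round-trips the profile to machine precision", {
  profiles <- list(c(94.4, 77.8, 61.1, 55.6), c(67.7, 48.7, 31.2, 16.0),
                   c(39.1, 22.1, 9.0, 3.0))
  tails <- list(27, NULL, NULL)
  for (i in seq_along(profiles)) {
    seg <- calibrate_piecewise_hazards(profiles[[i]],
                                       tail_median = tails[[i]])
    S <- piecewise_survival(seg, c(3, 6, 12, 24))
    expect_equal(S, profiles[[i]] / 100, tolerance = 1e-12)
    expect_equal(piecewise_survival(seg, 0), 1)
  }
})

test_that("a halving-every-3-months profile yields a constant hazard", {
  seg <- calibrate_piecewise_hazards(c(50, 25, 6.25, 100 * 2^-8))
  expect_equal(seg$hazards, rep(log(2) / 3, 5), tolerance = 1e-12)
})

test_that("analytic medians match the closed-form solves", {
  # intermediate-risk profile: median inside the 3-6 month segment
  seg_i <- calibrate_piecewise_hazards(c(67.7, 48.7, 31.2, 16.0))
  expect_equal(analytic_median(seg_i),
               3 + log(0.677 / 0.5) / (log(0.677 / 0.487) / 3),
               tolerance = 1e-12)
  expect_equal(round(analytic_median(seg_i)), 6)
  # high-risk profile: median inside the first segment
  seg_h <- calibrate_piecewise_hazards(c(39.1, 22.1, 9.0, 3.0))
  expect_equal(analytic_median(seg_h), 3 * log(0.5) / log(0.391),
               tolerance = 1e-12)
  expect_equal(round(analytic_median(seg_h)), 2)
  # low-risk tail calibrated to a 27-month median
  seg_l <- calibrate_piecewise_hazards(c(94.4, 77.8, 61.1, 55.6),
                                       tail_median = 27)
  expect_equal(analytic_median(seg_l), 27, tolerance = 1e-12)
  # plain exponential
  expect_equal(analytic_median(hazard_segments(c(0, Inf), log(2) / 6)), 6)
})

test_that("time rescaling divides the median by the scale factor", {
  # scaling hazards by c while shrinking breakpoints by c gives
  # S'(t) = S(ct), so every quantile -- the median included -- scales by 1/c
  seg <- calibrate_piecewise_hazards(c(67.7, 48.7, 31.2, 16.0))
  for (c_ in c(0.5, 2, 3)) {
    scaled <- hazard_segments(seg$breakpoints / c_, seg$hazards * c_)
    expect_equal(analytic_median(scaled), analytic_median(seg) / c_,
                 tolerance = 1e-10)
  }
  # for a single exponential segment, hazard scaling alone suffices
  expect_equal(analytic_median(hazard_segments(c(0, Inf), 2 * log(2) / 6)),
               3)
})

test_that("survival and quantile are mutually inverse", {
  seg <- calibrate_piecewise_hazards(c(94.4, 77.8, 61.1, 55.6),
                                     tail_median = 27)
  for (s in c(0.9, 0.7, 0.5, 0.3, 0.05)) {
    expect_equal(piecewise_survival(seg, piecewise_quantile(seg, s)), s,
                 tolerance = 1e-12)
  }
  # survival is strictly decreasing
  ts <- seq(0, 60, by = 1.5)
  expect_true(all(diff(piecewise_survival(seg, ts)) < 0))
})

test_that("invalid profiles are rejected", {
  expect_error(calibrate_piecewise_hazards(c(50, 60, 30, 10)),
               "strictly decreasing")
  expect_error(calibrate_piecewise_hazards(c(94.4, 77.8, 61.1, 55.6)),
               "tail_median")
  expect_error(calibrate_piecewise_hazards(c(94.4, 77.8, 61.1, 55.6),
                                           tail_median = 20), "exceed")
  expect_error(calibrate_piecewise_hazards(c(39.1, 22.1, 9.0, 3.0),
                                           tail_median = 40),
               "already determined")
  expect_error(calibrate_piecewise_hazards(c(110, 80, 50, 20)), "in \\(0")
  expect_error(hazard_segments(c(0, 3, Inf), c(-1, 1)), "positive")
  expect_error(hazard_segments(c(1, 3, Inf), c(1, 1)), "start at 0")
})
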