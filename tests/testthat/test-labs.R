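test_that("albumin-corrected calcium follows the Payne rule", {
  expect_equal(corrected_calcium(10.0, 4.0), 10.0)  # identity at the pivot
  expect_equal(corrected_calcium(9.0, 3.0), 9.8)
  expect_equal(corrected_calcium(9.5, 2.5), 10.7)   # crosses 10.3
  # no downward correction above the pivot
  expect_equal(corrected_calcium(9.5, 4.8), 9.5)
  # identity at pivot for a grid of calcium values
  for (ca in seq(7, 12, by = 0.5)) {
    expect_equal(corrected_calcium(ca, 4.0), ca)
    expect_gte(corrected_calcium(ca, 3.1), ca)      # never below measured
  }
})

test_that("missing albumin leaves calcium uncorrected with an annotation", {
  out <- corrected_calcium(9.7, NA)
  expect_equal(as.numeric(out), 9.7)
  expect_true(attr(out, "uncorrected"))
  expect_error(corrected_calcium(NA, 4.0), "calcium")
  expect_error(corrected_calcium(9.0, 0), "albumin")
})

test_that("lab categorization applies tier precedence and thresholds", {
  expect_equal(categorize_labs(normal_panel()), "normal")
  expect_equal(categorize_labs(normal_panel(crp = 1.2)), "abnormal")
  expect_equal(categorize_labs(normal_panel(ldh = 250)), "abnormal")
  expect_equal(categorize_labs(normal_panel(albumin = 3.69)), "abnormal")
  expect_equal(categorize_labs(normal_panel(bilirubin = 1.4)), "critical")
  # critical tier dominates a simultaneous abnormal crossing
  expect_equal(categorize_labs(normal_panel(platelets = 80000, crp = 5.0)),
               "critical")
  # calcium is compared after albumin correction: 9.5 + 0.8*1.5 = 10.7
  expect_equal(categorize_labs(normal_panel(calcium = 9.5, albumin = 2.5)),
               "critical")
})

test_that("incomplete panels without crossings are undetermined", {
  only_crp <- lab_panel(crp = 0.1)
  expect_equal(categorize_labs(only_crp), "undetermined")
  # but a crossing decides the category even with other analytes missing
  expect_equal(categorize_labs(lab_panel(crp = 2.0)), "abnormal")
  expect_equal(categorize_labs(lab_panel(platelets = 50000)), "critical")
})

test_that("lab categorization is idempotent and order-independent", {
  panels <- list(normal_panel(), normal_panel(crp = 1.2),
                 normal_panel(platelets = 80000), lab_panel(crp = 0.1))
  for (p in panels) {
    once <- categorize_labs(p)
    expect_identical(categorize_labs(p), once)
  }
  # order of analyte specification does not matter
  a <- lab_panel(crp = 5, platelets = 80000)
  b <- lab_panel(platelets = 80000, crp = 5)
  expect_identical(categorize_labs(a), categorize_labs(b))
})

test_that("the two-month validity window discards stale measurements", {
  rt <- as.Date("2010-06-01")
  fresh <- normal_panel(measured_on = rt - 30)
  stale <- normal_panel(measured_on = rt - 90)
  future <- normal_panel(measured_on = rt + 5)
  expect_equal(categorize_labs(fresh, rt_start = rt), "normal")
  expect_equal(categorize_labs(stale, rt_start = rt), "undetermined")
  expect_equal(categorize_labs(future, rt_start = rt), "undetermined")
  # boundary: exactly 61 days before is still valid
  expect_equal(categorize_labs(normal_panel(measured_on = rt - 61),
                               rt_start = rt), "normal")
  # per-analyte dates: one stale analyte only blanks that analyte
  p <- normal_panel(crp = 5,
                    measured_on = c(crp = rt - 90, ldh = rt - 10,
                                    albumin = rt - 10, platelets = rt - 10,
                                    calcium = rt - 10, bilirubin = rt - 10))
  expect_equal(categorize_labs(p, rt_start = rt), "undetermined")
})
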