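test_that("product-limit arithmetic on the three-observation example", {
  # death at 1, censored at 2, death at 3: S(1) = 2/3, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km_median(km), 3)
})

test_that("degenerate inputs: all censored, single death, empty", {
  km <- km_estimate(c(4, 9, 2), c(0, 0, 0))
  expect_true(attr(km, "all_censored"))
  expect_equal(survival_probability_at(km, c(0, 1, 2)), c(1, 1, 1))
  expect_equal(km_median(km), Inf)

  km1 <- km_estimate(5, 1)
  expect_equal(km1$surv, 0)
  expect_equal(km_median(km1), 5)

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "non-negative")
})

test_that("censoring at a death time keeps the censored subject at risk", {
  # death and censoring both at t=2 among 3 subjects: n_risk at 2 is 3
  km <- km_estimate(c(2, 2, 5), c(1, 0, 1))
  expect_equal(km$n_risk[1], 3L)
  expect_equal(km$surv, c(2 / 3, 0))
})

test_that("step-function evaluation interpolates and refuses to extrapolate", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(survival_probability_at(km, 0), 1)
  expect_equal(survival_probability_at(km, 0.99), 1)
  expect_equal(survival_probability_at(km, 2), 2 / 3)
  expect_true(is.na(survival_probability_at(km, 3.5)))  # beyond follow-up
  expect_error(survival_probability_at(km, -1), "non-negative")
})

test_that("without censoring the KM curve equals the empirical survival", {
  set.seed(101)
  for (rep in 1:5) {
    t <- round(rexp(40, 0.3), 2)
    km <- km_estimate(t, rep(1, 40))
    emp <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
    expect_equal(km$surv, emp)
  }
})

test_that("KM curve is non-increasing with values in [0, 1]", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 60
    t <- round(rexp(n, 0.2), 1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1L
    km <- km_estimate(t, ev)
    expect_true(all(diff(km$surv) <= 1e-12))
    expect_true(all(km$surv >= 0 & km$surv <= 1))
    # running-product identity
    expect_equal(km$surv, cumprod(1 - km$n_event / km$n_risk))
  }
})

test_that("KM agrees with the survival package on censored data", {
  skip_if_not_installed("survival")
  set.seed(5)
  t <- round(rexp(80, 0.15), 1)
  ev <- rbinom(80, 1, 0.6)
  km <- km_estimate(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  ref <- summary(sf, times = km$time)
  expect_equal(km$surv, ref$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, ref$n.risk)
})

test_that("median follow-up among survivors uses censored patients only", {
  expect_equal(median_follow_up_survivors(c(10, 42, 100, 3), c(0, 0, 0, 1)),
               42)
  expect_equal(median_follow_up_survivors(7, 0), 7)
  expect_equal(median_follow_up_survivors(c(10, 20, 1), c(0, 0, 1)), 15)
  expect_warning(out <- median_follow_up_survivors(c(2, 3), c(1, 1)),
                 "no censored")
  expect_true(is.na(out))
})

test_that("event coding accepts died/censored strings", {
  a <- km_estimate(c(1, 2, 3), c("died", "censored", "died"))
  b <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(a$surv, b$surv)
  expect_error(km_estimate(1, "lost"), "died/censored")
})
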