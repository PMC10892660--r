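test_that("depletion half-life scales to intrinsic clearance", {
  expect_equal(round(clint_from_halflife(34.8, 10), 2), 1.99)
  expect_equal(clint_from_halflife(log(2), 1000), 1)
  expect_equal(round(clint_from_halflife(20, 10), 2), 3.47)
  expect_error(clint_from_halflife(0, 10), "positive")
  expect_error(clint_from_halflife(10, -1), "positive")
})

test_that("clint is inversely proportional to t1/2 and enzyme level", {
  set.seed(7)
  for (i in 1:20) {
    t12 <- stats::runif(1, 1, 200); e <- stats::runif(1, 1, 100)
    f <- stats::runif(1, 1.1, 5)
    expect_equal(clint_from_halflife(t12 * f, e),
                 clint_from_halflife(t12, e) / f)
    expect_equal(clint_from_halflife(t12, e * f),
                 clint_from_halflife(t12, e) / f)
  }
})

test_that("depletion fitting recovers a noiseless decay exactly", {
  tt <- c(0, 5, 10, 20, 30)
  d <- data.frame(time_min = tt,
                  fraction_remaining = exp(-log(2) / 34.8 * tt))
  fit <- fit_depletion(d)
  expect_equal(fit$t_half_min, 34.8, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate[1], 34.8, tolerance = 1e-9)
})

test_that("non-decaying or underdetermined depletion data are rejected", {
  flat <- data.frame(time_min = c(0, 5, 10, 20, 30),
                     fraction_remaining = rep(1, 5))
  expect_error(fit_depletion(flat), "no measurable depletion")
  expect_error(fit_depletion(data.frame(time_min = c(0, 5),
                                        fraction_remaining = c(1, 0.5))),
               "3 distinct timepoints")
  expect_error(fit_depletion(data.frame(time_min = c(0, 5, 10),
                                        fraction_remaining = c(1, 0.5, -1))),
               "positive")
})

test_that("depletion recovery from noisy triplicates stays within 10%", {
  assay <- generate_invitro("depletion", truth = list(t_half_min = 34.8),
                            noise_cv = 0.05, seed = 101)
  fit <- fit_depletion(assay)
  expect_lt(abs(fit$t_half_min - 34.8) / 34.8, 0.10)
})

test_that("IC50 fitting recovers its own generating model", {
  conc <- c(0, 0.1, 0.3, 1, 3, 10, 30, 60, 100)
  d1 <- data.frame(inhibitor_uM = conc,
                   pct_control = 100 / (1 + (conc / 2.08)^1))
  f1 <- fit_ic50(d1)
  expect_equal(f1$ic50_um, 2.08, tolerance = 1e-6)
  expect_equal(f1$hill_slope, 1, tolerance = 1e-5)
  d2 <- data.frame(inhibitor_uM = conc,
                   pct_control = 100 / (1 + (conc / 8.59)^1.3))
  f2 <- fit_ic50(d2)
  expect_equal(f2$ic50_um, 8.59, tolerance = 1e-6)
  expect_equal(f2$hill_slope, 1.3, tolerance = 1e-5)
  expect_gt(glance(f2)$r_squared, 0.999)
})

test_that("rising dose-response curves are rejected as non-inhibition", {
  conc <- c(0, 0.1, 0.3, 1, 3, 10, 30, 60, 100)
  d <- data.frame(inhibitor_uM = conc, pct_control = 100 + conc)
  expect_error(fit_ic50(d), "not an inhibition curve")
  expect_error(fit_ic50(data.frame(inhibitor_uM = c(0, 1, 10),
                                   pct_control = c(100, 50, 10))),
               "5 concentration levels")
})

test_that("IC50-to-Ki scaling follows the stated ratio rule", {
  expect_equal(ki_from_ic50(8.59, 2.08, 0.06), 0.2477884615,
               tolerance = 1e-9)
  expect_equal(ki_from_ic50(3.3, 3.3, 0.42), 0.42)
  expect_error(ki_from_ic50(-1, 1, 1), "positive")
  # Cheng-Prusoff anchor: S = Km halves the IC50
  expect_equal(cheng_prusoff(4, 2.5, 2.5), 2)
})
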