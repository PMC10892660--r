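test_that("MRD is 1 for identity and follows the log-RMS definition", {
  obs <- data.frame(time_h = 1:3, conc_ng_per_ml = c(10, 5, 2))
  expect_equal(mrd(obs, obs), 1)
  one <- data.frame(time_h = 1, conc_ng_per_ml = 10)
  expect_equal(mrd(one, data.frame(time_h = 1, conc_ng_per_ml = 1)), 10)
  two_obs <- data.frame(time_h = 1:2, conc_ng_per_ml = c(10, 5))
  two_pred <- data.frame(time_h = 1:2, conc_ng_per_ml = c(5, 5))
  expect_equal(mrd(two_obs, two_pred), 1.632527, tolerance = 1e-6)
  expect_error(mrd(obs, data.frame(time_h = 9, conc_ng_per_ml = 1)),
               "common timepoints")
  expect_error(mrd(obs, data.frame(time_h = 1:3,
                                   conc_ng_per_ml = c(1, 0, 1))),
               "positive")
})

test_that("GMFE uses absolute log fold errors and is inversion-symmetric", {
  expect_equal(round(gmfe(c(2.05, 1.46)), 2), 1.73)
  expect_equal(gmfe(c(1, 1)), 1)
  expect_equal(gmfe(c(2, 0.5)), 2)
  set.seed(11)
  r <- stats::runif(20, 0.2, 5)
  expect_equal(gmfe(r), gmfe(1 / r))
  expect_error(gmfe(numeric()), "nonempty")
  expect_error(gmfe(c(1, -2)), "positive")
})

test_that("DDI ratios reproduce the observed and predicted study tables", {
  obs <- reported_table("rat_victim_ddi_observed")
  r <- ddi_ratios(
    data.frame(cmax = obs$alone_mean[obs$parameter == "Cmax"],
               auc_inf = obs$alone_mean[obs$parameter == "AUCinf"]),
    data.frame(cmax = obs$combo_mean[obs$parameter == "Cmax"],
               auc_inf = obs$combo_mean[obs$parameter == "AUCinf"]))
  expect_equal(round(r$ddi_auc_ratio, 2), 2.60)
  expect_equal(round(r$ddi_cmax_ratio, 2), 2.85)
  same <- data.frame(cmax = 50, auc_inf = 200)
  expect_equal(unlist(ddi_ratios(same, same)),
               c(ddi_auc_ratio = 1, ddi_cmax_ratio = 1))
  expect_error(ddi_ratios(data.frame(cmax = 1), same), "auc_inf")
})

test_that("fold classification bands are symmetric in log space", {
  fc <- fold_classification(c(144, 100, 205, 100 / 2.05, 100 * 1.24),
                            c(98.5, 100, 100, 100, 100))
  expect_equal(as.character(fc$pairs$band),
               c("within 2-fold", "within 1.25-fold", "outside 2-fold",
                 "outside 2-fold", "within 1.25-fold"))
  expect_equal(sum(fc$counts$n), 5)
  expect_false(fc$pass_2fold)
  expect_error(fold_classification(-1, 1), "positive")
})

test_that("MRD and GMFE are invariant to common unit rescaling", {
  obs <- data.frame(time_h = 1:4, conc_ng_per_ml = c(12, 8, 4, 2))
  pred <- data.frame(time_h = 1:4, conc_ng_per_ml = c(10, 9, 5, 1.5))
  sc_obs <- obs; sc_obs$conc_ng_per_ml <- obs$conc_ng_per_ml * 1000
  sc_pred <- pred; sc_pred$conc_ng_per_ml <- pred$conc_ng_per_ml * 1000
  expect_equal(mrd(sc_obs, sc_pred), mrd(obs, pred))
  p <- c(144, 177); o <- c(98.5, 157)
  expect_equal(gmfe((p * 7) / (o * 7)), gmfe(p / o))
})

test_that("evaluation report applies the 2-fold adequacy flags", {
  rep <- evaluation_report(
    predicted_params = c(cmax = 144, auc_inf = 177),
    observed_params = c(cmax = 98.5, auc_inf = 157))
  expect_true(rep$pass_gmfe)
  expect_true(rep$folds$pass_2fold)
  expect_equal(round(rep$ratios$ratio[rep$ratios$parameter == "cmax"], 2),
               1.46)
})

test_that("a zero-variability population collapses to the point estimate", {
  pi <- pi_cv0()
  expect_equal(pi$lo, pi$point, tolerance = 1e-12)
  expect_equal(pi$hi, pi$point, tolerance = 1e-12)
})

test_that("interval width grows with the population CV and covers the point", {
  sc <- pbpk_scenario(sxg(), "rat", 5, duration_h = 6,
                      solver = coarse_solver)
  lo_cv <- prediction_interval(sc, list(
    n_subjects = 12, seed = 9, cv = c("compound.clint.CYP3A2" = 0.1)))
  hi_cv <- prediction_interval(sc, list(
    n_subjects = 12, seed = 9, cv = c("compound.clint.CYP3A2" = 0.4)))
  sel <- lo_cv$point > 1 # compare where the profile is informative
  expect_true(all((hi_cv$hi - hi_cv$lo)[sel] >= (lo_cv$hi - lo_cv$lo)[sel]))
  # the 95% band from a unit-median population covers the point trajectory
  cover <- mean(hi_cv$lo[sel] <= hi_cv$point[sel] &
                  hi_cv$point[sel] <= hi_cv$hi[sel])
  expect_gte(cover, 0.95)
  # deterministic given the seed
  again <- prediction_interval(sc, list(
    n_subjects = 12, seed = 9, cv = c("compound.clint.CYP3A2" = 0.4)))
  expect_identical(hi_cv$lo, again$lo)
})
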