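test_that("the assembled system has the documented state layout", {
  model <- build_model(sxg(), rat_phys())
  n <- nrow(rat_phys()$organs)
  expect_equal(model$n_states, 4 * n + 16)
  expect_length(model$state_names, model$n_states)
  expect_true(all(c("arterial_plasma", "venous_plasma", "stomach_dissolved",
                    "si3_undissolved", "metabolized", "urine",
                    "hepatic_eliminated", "feces") %in% model$state_names))
  # liver receives hepatic artery + portal (gut, spleen) inflow
  org <- model$physiology$organs
  hct <- model$physiology$hematocrit
  q_liv_out_pl <- sum(org$flow_ml_h[org$organ %in%
                                      c("liver", "gut", "spleen")]) *
    (1 - hct)
  i_liver <- which(org$organ == "liver")
  expect_equal(model$M[model$i_ven_pl, model$idx$pl[i_liver]],
               q_liv_out_pl / model$v$pl[i_liver])
  # gut outflow feeds the liver, not the venous pool
  i_gut <- which(org$organ == "gut")
  expect_equal(model$M[model$i_ven_pl, model$idx$pl[i_gut]], 0)
  expect_gt(model$M[model$idx$pl[i_liver], model$idx$pl[i_gut]], 0)
})

test_that("metabolic flux follows the abundance-scaled unit arithmetic", {
  expect_equal(round(metabolism_flux(1.99, 45248, 1), 2), 90.04)
  expect_equal(metabolism_flux(1.99, 45248, 0), 0)
  expect_equal(metabolism_flux(1.99, 45248, 2),
               2 * metabolism_flux(1.99, 45248, 1))
  expect_error(metabolism_flux(-1, 1, 1), "nonnegative")
})

test_that("zero dose yields an identically zero trajectory", {
  model <- build_model(sxg(), rat_phys())
  sim <- simulate_pbpk(model, dose_event("oral", 1)[0, ], duration_h = 1)
  expect_true(all(sim$states == 0))
  expect_true(all(sim$profile$conc_ng_per_ml == 0))
})

test_that("without elimination an IV bolus equilibrates all unbound pools", {
  probe <- toy_compound(logd = 0.5, fu = 0.5)
  phys <- rat_phys()
  model <- build_model(probe, phys,
                       options = list(k_endo_per_h = 1e5, k_rbc_per_h = 1e5))
  sim <- simulate_pbpk(model, dose_event("iv_bolus", 2), duration_h = 24,
                       solver = list(dt_out = 0.05))
  last <- sim$states[nrow(sim$states), , drop = FALSE]
  cu <- unlist(lapply(phys$organs$organ, function(o) {
    c(pbpkddi:::unbound_conc(model, last, "plasma", o),
      pbpkddi:::unbound_conc(model, last, "interstitial", o),
      pbpkddi:::unbound_conc(model, last, "intracellular", o))
  }))
  cu <- c(cu, last[, "venous_plasma"] / model$v$ven_pl * model$fu)
  expect_lt(diff(range(cu)) / mean(cu), 1e-3)
})

test_that("the engine reduces to the one-compartment closed form", {
  expect_lt(onecomp_max_dev(), 0.001)
})

test_that("mass is conserved to solver precision throughout", {
  mb <- mass_balance(rat_sxg_sim())
  expect_lt(max(mb$rel_error[mb$administered_nmol > 0]), 1e-6)
})

test_that("AUC scales linearly with dose under first-order clearance", {
  expect_lt(doseprop_rel_dev(), 1e-6)
})

test_that("tightening solver tolerances leaves Cmax and AUC unchanged", {
  base <- simulate_scenario(pbpk_scenario(sxg(), "rat", 5, duration_h = 12,
                                          solver = list(dt_out = 0.02)))
  tight <- simulate_scenario(pbpk_scenario(
    sxg(), "rat", 5, duration_h = 12,
    solver = list(dt_out = 0.02, rtol = 1e-9, atol = 1e-11)))
  pk_b <- nca_single(base$profile)
  pk_t <- nca_single(tight$profile)
  expect_lt(abs(pk_b$cmax / pk_t$cmax - 1), 0.001)
  expect_lt(abs(pk_b$auc_last / pk_t$auc_last - 1), 0.001)
})

test_that("repeated dosing settles into a periodic steady state", {
  doses <- purrr::map_dfr(seq(0, 30, by = 6), function(tt)
    dose_event("oral", 5, time_h = tt))
  model <- build_model(sxg(), rat_phys())
  sim <- simulate_pbpk(model, doses, duration_h = 36,
                       solver = list(dt_out = 0.02))
  auc_win <- function(t1, t2) {
    sel <- sim$profile$time_h >= t1 & sim$profile$time_h <= t2
    pbpkddi:::auc_trapezoid(sim$profile$time_h[sel],
                            sim$profile$conc_ng_per_ml[sel])
  }
  expect_lt(abs(auc_win(24, 30) / auc_win(30, 36) - 1), 1e-3)
})

test_that("rat oral exposure reproduces the reported scale", {
  pk <- nca_single(rat_sxg_sim()$profile, dose = 5)
  # 2-fold adequacy band around the reported model prediction
  expect_true(fold_classification(pk$cmax, 144)$pass_2fold)
  expect_true(fold_classification(pk$auc_inf, 177)$pass_2fold)
})

test_that("dosing and duration inconsistencies are rejected", {
  model <- build_model(sxg(), rat_phys())
  expect_error(simulate_pbpk(model, dose_event("oral", 5, time_h = 30),
                             duration_h = 24), "cover all dose times")
  expect_error(dose_event("oral", -5), "positive")
  expect_error(simulate_pbpk(model, dose_event("oral", 5), duration_h = 24,
                             solver = list(rtol = -1)), "positive")
})
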