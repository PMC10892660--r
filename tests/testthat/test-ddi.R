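test_that("apparent intrinsic clearance follows competitive inhibition", {
  expect_equal(apparent_clint(1.99, 0, 0.39), 1.99)
  expect_equal(apparent_clint(2, 0.39, 0.39), 1)
  expect_equal(apparent_clint(1.99, 0.0121, 0.39), 1.930117,
               tolerance = 1e-6)
  expect_error(apparent_clint(1, -0.1, 0.5), "nonnegative")
  expect_error(apparent_clint(1, 0.1, 0), "positive")
})

test_that("the static index reproduces both species' screening values", {
  inputs <- reported_table("static_model_inputs")
  idx <- vapply(seq_len(nrow(inputs)), function(i) {
    static_index(inputs$perpetrator_cmax_ng_ml[i],
                 inputs$fraction_unbound[i],
                 inputs$molecular_weight_g_mol[i],
                 inputs$ki_um[i])
  }, numeric(1))
  expect_equal(round(idx[inputs$species == "rat"], 2), 1.03)
  expect_equal(round(idx[inputs$species == "human"], 2), 1.01)
  # no free inhibitor, no interaction
  expect_equal(static_index(69.3, 1e-9, 479.59, 0.39), 1, tolerance = 1e-6)
})

test_that("scenario validation requires a matching inhibitable enzyme", {
  no_inh <- toy_compound()
  expect_error(ddi_scenario(sxg(), no_inh, "rat", 5, 15),
               "no inhibition")
  # victim without CYP-mediated clearance cannot be inhibited
  expect_error(ddi_scenario(toy_compound(), ncd(), "rat", 5, 15),
               "none of the perpetrator's inhibited enzymes")
})

test_that("a zero perpetrator dose leaves the victim untouched", {
  res <- fixture("ddi_zero_dose", simulate_ddi(rat_ddi_scenario(perp_dose = 0)))
  expect_lt(abs(res$ratios$ddi_auc_ratio - 1), 1e-6)
  expect_lt(abs(res$ratios$ddi_cmax_ratio - 1), 1e-6)
  expect_true(all(res$perp_profile$conc_ng_per_ml == 0))
})

test_that("infinite Ki decouples the two compounds completely", {
  res <- rat_ddi_coarse(ki_factor = 1e7)
  expect_lt(abs(res$ratios$ddi_auc_ratio - 1), 1e-3)
  expect_lt(abs(res$ratios$ddi_cmax_ratio - 1), 1e-3)
  # victim trajectory unaffected by the coupling
  rel <- abs(res$combo_profile$conc_ng_per_ml -
               res$alone_profile$conc_ng_per_ml) /
    pmax(res$alone_profile$conc_ng_per_ml, 1e-6)
  expect_lt(stats::median(rel), 1e-4)
})

test_that("the interaction strengthens with dose and weakens with Ki", {
  r0 <- fixture("ddi_zero_dose", simulate_ddi(rat_ddi_scenario(perp_dose = 0)))
  r_half <- rat_ddi_coarse(perp_dose = 7.5)
  r_full <- rat_ddi_coarse(perp_dose = 15)
  expect_true(r0$ratios$ddi_auc_ratio - 1e-6 <= r_half$ratios$ddi_auc_ratio)
  expect_lt(r_half$ratios$ddi_auc_ratio, r_full$ratios$ddi_auc_ratio)
  r_ki10 <- rat_ddi_coarse(ki_factor = 10)
  r_kiinf <- rat_ddi_coarse(ki_factor = 1e7)
  expect_gt(r_full$ratios$ddi_auc_ratio, r_ki10$ratios$ddi_auc_ratio)
  expect_gt(r_ki10$ratios$ddi_auc_ratio,
            r_kiinf$ratios$ddi_auc_ratio - 1e-6)
})

test_that("weak static inhibition implies a small dynamic interaction", {
  res <- rat_ddi_coarse(ki_factor = 10) # Ki = 3.9 uM
  idx <- static_index(max(res$perp_profile$conc_ng_per_ml),
                      0.084, 479.59, 0.39 * 10)
  expect_lt(idx, 1.05)
  expect_lt(res$ratios$ddi_auc_ratio, 1.25)
})

test_that("the rat co-administration scenario reproduces the reported DDI", {
  res <- rat_ddi_res()
  expect_gt(res$ratios$ddi_auc_ratio, 1)
  expect_true(fold_classification(res$ratios$ddi_auc_ratio, 2.54)$pass_2fold)
  # victim exposure rises under co-administration
  expect_gt(res$pk_combo$cmax, res$pk_alone$cmax)
  expect_identical(nrow(tidy(res)), 2L)
  expect_equal(glance(res)$ddi_auc_ratio, res$ratios$ddi_auc_ratio)
})
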