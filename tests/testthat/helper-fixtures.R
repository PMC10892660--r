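# Shared fixtures. Expensive simulations are computed once per test run
# and cached; property grids use a coarser (but verified-equivalent)
# solver setting than the engine default.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

coarse_solver <- list(rtol = 1e-6, atol = 1e-8, dt_out = 0.05)

sxg <- function() fixture("sxg", read_compound("saxagliptin"))
ncd <- function() fixture("ncd", read_compound("nicardipine"))
rat_phys <- function() fixture("rat_phys", load_physiology("rat"))

# rat victim-alone simulation at engine/solver defaults
rat_sxg_sim <- function() fixture("rat_sxg_sim", {
  simulate_scenario(pbpk_scenario(sxg(), "rat", 5, duration_h = 24))
})

rat_ddi_scenario <- function(solver = list(), perp_dose = 15,
                             ki_factor = 1) {
  sc <- ddi_scenario(sxg(), ncd(), "rat", victim_dose = 5,
                     perp_dose = perp_dose, duration_h = 24,
                     solver = solver)
  if (ki_factor != 1) sc <- perturb_scenario(sc, "perpetrator.ki.CYP3A2",
                                             ki_factor)
  sc
}

# reference rat DDI co-simulation at engine/solver defaults
rat_ddi_res <- function() fixture("rat_ddi_res", {
  simulate_ddi(rat_ddi_scenario())
})

# coarse-solver DDI runs over perturbed conditions, cached by key
rat_ddi_coarse <- function(perp_dose = 15, ki_factor = 1) {
  key <- sprintf("ddi_coarse_%g_%g", perp_dose, ki_factor)
  fixture(key, simulate_ddi(
    rat_ddi_scenario(solver = coarse_solver, perp_dose = perp_dose,
                     ki_factor = ki_factor)))
}

# analytic monoexponential profile (C0 = 100 ng/mL, k = 0.1 /h)
monoexp_profile <- function() {
  tt <- seq(0, 72, by = 0.25)
  data.frame(time_h = tt, conc_ng_per_ml = 100 * exp(-0.1 * tt))
}

# one-compartment reduction: maximum relative deviation of the simulated
# plasma profile from C0*exp(-k*t) for t >= 0.5 h (cached)
onecomp_max_dev <- function() fixture("onecomp_max_dev", {
  cl_ml_min_kg <- 1
  probe <- toy_compound(fu = 1, clearance = list(
    list(kind = "renal", species = "rat",
         renal_clearance_ml_min_kg = cl_ml_min_kg)))
  # fast mixing; negligible hematocrit so the erythrocyte phase (whose
  # partition is composition-based, not overridable) cannot bias V
  phys <- load_physiology("rat", overrides = list(
    cardiac_output_ml_min = 8000, hematocrit = 1e-6))
  kp1 <- stats::setNames(rep(1, nrow(phys$organs)), phys$organs$organ)
  model <- build_model(probe, phys,
                       kps = partition_coefficients(probe, phys,
                                                    overrides = kp1),
                       options = list(k_endo_per_h = 1e5, k_rbc_per_h = 1e5))
  sim <- simulate_pbpk(model, dose_event("iv_bolus", 2), duration_h = 12,
                       solver = list(dt_out = 0.05))
  v_total <- sum(phys$organs$volume_ml) + sum(phys$blood)
  k <- cl_ml_min_kg * phys$body_weight * 60 / v_total
  dose_nmol <- pbpkddi:::mg_to_nmol(2 * phys$body_weight,
                                    probe$molecular_weight)
  sel <- sim$profile$time_h >= 0.5
  expected <- dose_nmol / v_total * exp(-k * sim$profile$time_h[sel]) *
    probe$molecular_weight
  max(abs(sim$profile$conc_ng_per_ml[sel] - expected) / expected)
})

# dose-proportionality: |AUC(2d)/(2*AUC(d)) - 1| under linear clearance
doseprop_rel_dev <- function() fixture("doseprop_rel_dev", {
  run <- function(dose) {
    sim <- simulate_scenario(pbpk_scenario(
      sxg(), "rat", dose, duration_h = 12, solver = list(dt_out = 0.02)))
    pbpkddi:::auc_trapezoid(sim$profile$time_h, sim$profile$conc_ng_per_ml)
  }
  abs(run(4) / (2 * run(2)) - 1)
})

# sensitivity of exposure to dose under linear disposition (cached)
dose_scan <- function() fixture("dose_scan", {
  sensitivity_scan(pbpk_scenario(sxg(), "rat", 5, duration_h = 24,
                                 solver = coarse_solver), "dose")
})

# Monte-Carlo interval at zero population variability (cached)
pi_cv0 <- function() fixture("pi_cv0", {
  sc <- pbpk_scenario(sxg(), "rat", 5, duration_h = 6,
                      solver = coarse_solver)
  prediction_interval(sc, list(n_subjects = 3, seed = 5,
                               cv = c("compound.clint.CYP3A2" = 0)))
})

# a neutral reference compound for partitioning/engine limit checks
toy_compound <- function(logd = 0, fu = 1, clearance = list()) {
  compound(name = "probe", molecular_weight_g_mol = 300,
           lipophilicity_logd74 = logd, pka = 7, compound_type = "neutral",
           solubility_mg_per_ml = 10, fraction_unbound = list(rat = fu),
           intestinal_permeability_1e6_cm_s = 1,
           cellular_permeability = list(value = 100, unit = "1e-6 cm/s"),
           clearance = clearance)
}
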