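# Seeded synthetic-data generators: virtual PK studies with known ground
# truth (for recovery tests and worked examples) and in vitro assay
# datasets matching the depletion / inhibition designs consumed by the
# IVIVE fitters.

#' Describe a virtual PK study design
#'
#' @param groups tibble with columns `name`, `arm` (one of
#'   `"victim_alone"`, `"perpetrator_alone"`, `"coadministration"`) and
#'   `n` (subjects, >= 1).
#' @param sampling_times_h sampling schedule, h (strictly increasing).
#' @param prop_cv proportional residual-error CV (default 0.10).
#' @param add_sd additive residual error SD, ng/mL (default 1).
#' @param iiv_cv named vector of lognormal inter-individual CVs; names
#'   are scenario parameter paths (see [perturb_scenario()]).
#' @param seed mandatory RNG seed, recorded in every output.
#' @param lloq optional lower limit of quantification, ng/mL;
#'   concentrations below it are reported as 0 and flagged.
#' @return an object of class `study_design`.
#' @export
study_design <- function(groups, sampling_times_h,
                         prop_cv = 0.10, add_sd = 1,
                         iiv_cv = numeric(), seed, lloq = NULL) {
  stopifnot(is.data.frame(groups),
            all(c("name", "arm", "n") %in% names(groups)))
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  if (any(groups$n < 1)) abort("each group needs n >= 1")
  if (!all(groups$arm %in% c("victim_alone", "perpetrator_alone",
                             "coadministration"))) {
    abort("unknown study arm")
  }
  if (is.unsorted(sampling_times_h, strictly = TRUE)) {
    abort("sampling_times_h must be strictly increasing")
  }
  check_nonnegative(c(prop_cv, add_sd), "residual error")
  check_nonnegative(iiv_cv, "iiv_cv")
  structure(list(groups = as_tibble(groups),
                 sampling_times_h = sampling_times_h,
                 prop_cv = prop_cv, add_sd = add_sd,
                 iiv_cv = iiv_cv, seed = seed, lloq = lloq),
            class = "study_design")
}

# linear interpolation of a dense simulated profile at the sampling times
sample_profile <- function(profile, times_h) {
  stats::approx(profile$time_h, profile$conc_ng_per_ml, xout = times_h,
                rule = 2)$y
}

#' Generate a virtual PK study from a DDI scenario
#'
#' Per subject, inter-individual lognormal parameter variability is
#' applied to the scenario (unit median), the arm's profile is simulated,
#' sampled at the design's schedule, and residual error
#' (proportional + additive, truncated at zero and at the LLOQ if set)
#' is added. The ground-truth log carries every subject's parameter
#' factors and noiseless concentrations, so all observations can be
#' re-derived given the seed.
#'
#' @param design a [study_design()].
#' @param scenario a [ddi_scenario()] defining compounds, doses, species.
#' @return list with `observations` (tibble: `subject`, `group`, `arm`,
#'   `time_h`, `conc_ng_per_ml`, `dose`, `below_lloq`), `truth` (list:
#'   per-subject parameter factors and noiseless concentrations) and
#'   `design`.
#' @export
generate_pk_study <- function(design, scenario) {
  stopifnot(inherits(design, "study_design"),
            inherits(scenario, "ddi_scenario"))
  iiv <- design$iiv_cv

  arm_profile <- function(sc, arm) {
    switch(arm,
      victim_alone = {
        vs <- pbpk_scenario(sc$victim, sc$species, sc$victim_dose,
                            per_kg = sc$per_kg, route = sc$route,
                            formulation = sc$victim_formulation,
                            body_weight = sc$body_weight,
                            duration_h = sc$duration_h,
                            dose_times_h = sc$dose_times_h,
                            physiology_overrides = sc$physiology_overrides,
                            engine_options = sc$engine_options,
                            solver = sc$solver)
        list(profile = simulate_scenario(vs)$profile, dose = sc$victim_dose)
      },
      perpetrator_alone = {
        ps <- pbpk_scenario(sc$perpetrator, sc$species, sc$perp_dose,
                            per_kg = sc$per_kg, route = sc$route,
                            formulation = sc$perp_formulation,
                            body_weight = sc$body_weight,
                            duration_h = sc$duration_h,
                            dose_times_h = sc$dose_times_h,
                            physiology_overrides = sc$physiology_overrides,
                            engine_options = sc$engine_options,
                            solver = sc$solver)
        list(profile = simulate_scenario(ps)$profile, dose = sc$perp_dose)
      },
      coadministration = {
        list(profile = simulate_ddi(sc)$combo_profile, dose = sc$victim_dose)
      })
  }

  withr_seed(design$seed, {
    obs <- list(); truth <- list()
    sid <- 0L
    for (g in seq_len(nrow(design$groups))) {
      grp <- design$groups[g, ]
      for (s in seq_len(grp$n)) {
        sid <- sid + 1L
        subject <- sprintf("%s_%02d", grp$name, s)
        factors <- stats::setNames(rep(1, length(iiv)), names(iiv))
        sc <- scenario
        for (p in names(iiv)) {
          if (iiv[[p]] > 0) {
            sdlog <- sqrt(log(1 + iiv[[p]]^2))
            factors[[p]] <- stats::rlnorm(1, -sdlog^2 / 2, sdlog)
            sc <- perturb_scenario(sc, p, factors[[p]])
          }
        }
        ap <- arm_profile(sc, grp$arm)
        clean <- sample_profile(ap$profile, design$sampling_times_h)
        noisy <- clean * (1 + design$prop_cv *
                            stats::rnorm(length(clean))) +
          design$add_sd * stats::rnorm(length(clean))
        noisy <- pmax(noisy, 0)
        below <- if (!is.null(design$lloq)) noisy < design$lloq else
          rep(FALSE, length(noisy))
        noisy[below] <- 0
        obs[[sid]] <- tibble(subject = subject, group = grp$name,
                             arm = grp$arm,
                             time_h = design$sampling_times_h,
                             conc_ng_per_ml = noisy, dose = ap$dose,
                             below_lloq = below)
        truth[[subject]] <- list(factors = factors,
                                 clean_conc_ng_per_ml = clean)
      }
    }
    list(observations = bind_rows(obs), truth = truth, design = design)
  })
}

#' Generate a synthetic in vitro assay dataset
#'
#' Reproduces the two bench designs consumed by the IVIVE fitters: a
#' triplicate substrate-depletion time course (0/5/10/20/30 min) or a
#' 9-concentration (0-100 uM) triplicate inhibition curve. Noise is
#' proportional (lognormal-free, truncated at 0); the 0-uM inhibition
#' control is 100% by construction.
#'
#' @param kind `"depletion"` or `"inhibition"`.
#' @param truth named list of true parameters: `t_half_min` for
#'   depletion; `ic50_um` and optional `hill_slope` (default 1) for
#'   inhibition.
#' @param noise_cv proportional noise CV (default 0.05).
#' @param seed mandatory RNG seed.
#' @param n_replicates replicates per point (default 3).
#' @return a tibble in the matching assay CSV format
#'   (`time_min`/`replicate`/`fraction_remaining` or
#'   `inhibitor_uM`/`replicate`/`pct_control`) with the truth and seed in
#'   attributes `truth` and `seed`.
#' @export
generate_invitro <- function(kind = c("depletion", "inhibition"), truth,
                             noise_cv = 0.05, seed, n_replicates = 3) {
  kind <- match.arg(kind)
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory")
  check_nonnegative(noise_cv, "noise_cv")
  out <- withr_seed(seed, {
    if (kind == "depletion") {
      check_positive(truth$t_half_min, "t_half_min")
      tt <- c(0, 5, 10, 20, 30)
      grid <- tidyr::expand_grid(time_min = tt,
                                 replicate = seq_len(n_replicates))
      clean <- exp(-log(2) / truth$t_half_min * grid$time_min)
      grid$fraction_remaining <-
        pmax(clean * (1 + noise_cv * stats::rnorm(nrow(grid))), 1e-6)
      grid
    } else {
      check_positive(truth$ic50_um, "ic50_um")
      h <- truth$hill_slope %||% 1
      conc <- c(0, 0.1, 0.3, 1, 3, 10, 30, 60, 100)
      grid <- tidyr::expand_grid(inhibitor_uM = conc,
                                 replicate = seq_len(n_replicates))
      clean <- 100 / (1 + (grid$inhibitor_uM / truth$ic50_um)^h)
      noisy <- pmax(clean * (1 + noise_cv * stats::rnorm(nrow(grid))), 0)
      noisy[grid$inhibitor_uM == 0] <- 100 # control defines 100%
      grid$pct_control <- noisy
      grid
    }
  })
  attr(out, "truth") <- truth
  attr(out, "seed") <- seed
  out
}
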