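# Scenario layer: a declarative description of one simulation (compound,
# species, dosing, duration) that can be rebuilt after parameter
# perturbation — the working currency of the sensitivity scan and the
# Monte-Carlo population layer.

#' Describe a single-compound simulation scenario
#'
#' @param compound a [compound()] object.
#' @param species `"rat"` or `"human"`.
#' @param dose dose amount (mg/kg with `per_kg = TRUE`, else mg).
#' @param per_kg interpret `dose` per kg body weight.
#' @param route `"oral"` or `"iv_bolus"`.
#' @param formulation formulation name on the compound (oral only).
#' @param body_weight kg; bundled reference weight when `NULL`.
#' @param duration_h simulated time span.
#' @param dose_times_h administration times (repeated dosing supported).
#' @param physiology_overrides passed to [load_physiology()].
#' @param kp_overrides passed to [partition_coefficients()].
#' @param engine_options,solver passed to [build_model()] /
#'   [simulate_pbpk()].
#' @return an object of class `pbpk_scenario`.
#' @export
pbpk_scenario <- function(compound, species, dose, per_kg = TRUE,
                          route = "oral", formulation = "solution",
                          body_weight = NULL, duration_h = 24,
                          dose_times_h = 0,
                          physiology_overrides = list(),
                          kp_overrides = NULL,
                          engine_options = list(), solver = list()) {
  stopifnot(inherits(compound, "pbpk_compound"))
  check_nonnegative(dose, "dose")
  structure(list(
    compound = compound, species = species, dose = dose, per_kg = per_kg,
    route = route, formulation = formulation, body_weight = body_weight,
    duration_h = duration_h, dose_times_h = dose_times_h,
    physiology_overrides = physiology_overrides,
    kp_overrides = kp_overrides,
    engine_options = engine_options, solver = solver
  ), class = "pbpk_scenario")
}

scenario_doses <- function(sc, compound, dose, formulation, route) {
  if (dose <= 0) {
    return(dose_event("oral", 1)[0, ])
  }
  purrr::map_dfr(sc$dose_times_h, function(tt) {
    dose_event(route = route, amount = dose, per_kg = sc$per_kg,
               time_h = tt, formulation = formulation)
  })
}

#' Simulate a scenario
#' @param sc a [pbpk_scenario()].
#' @return a `pbpk_sim`.
#' @export
simulate_scenario <- function(sc) {
  stopifnot(inherits(sc, "pbpk_scenario"))
  phys <- load_physiology(sc$species, sc$body_weight,
                          sc$physiology_overrides)
  kps <- partition_coefficients(sc$compound, phys, sc$kp_overrides)
  model <- build_model(sc$compound, phys, kps, sc$engine_options)
  doses <- scenario_doses(sc, sc$compound, sc$dose, sc$formulation, sc$route)
  simulate_pbpk(model, doses, sc$duration_h, sc$solver)
}

# plasma profile of the scenario's primary output (victim under
# co-administration for a DDI scenario)
scenario_profile <- function(sc) {
  if (inherits(sc, "pbpk_scenario")) {
    simulate_scenario(sc)$profile
  } else if (inherits(sc, "ddi_scenario")) {
    simulate_ddi(sc)$combo_profile
  } else {
    abort("scenario must be a pbpk_scenario or ddi_scenario")
  }
}

# --- parameter addressing --------------------------------------------------

# multiply one scalar parameter of a compound by `factor`
modify_compound <- function(cmp, key, factor, species, formulation = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  field <- parts[1]
  if (field == "fraction_unbound") {
    new <- cmp$fraction_unbound[[species]] * factor
    if (new > 1) {
      warn("fraction_unbound capped at 1 after perturbation")
      new <- 1
    }
    cmp$fraction_unbound[[species]] <- new
  } else if (field == "lipophilicity_logd74") {
    cmp$logd74 <- cmp$logd74 * factor
  } else if (field == "molecular_weight") {
    cmp$molecular_weight <- cmp$molecular_weight * factor
  } else if (field == "solubility") {
    cmp$solubility_mg_per_ml <- cmp$solubility_mg_per_ml * factor
  } else if (field == "intestinal_permeability") {
    cmp$peff_1e6_cm_s <- cmp$peff_1e6_cm_s * factor
  } else if (field == "cellular_permeability") {
    cmp$cellular_permeability$value <- cmp$cellular_permeability$value * factor
  } else if (field == "clint") {
    enz <- parts[2]
    hit <- FALSE
    for (k in seq_along(cmp$clearance)) {
      cl <- cmp$clearance[[k]]
      if (cl$kind == "enzyme_mediated" && identical(cl$enzyme, enz) &&
          (is.null(cl$species) || cl$species == species)) {
        cmp$clearance[[k]]$clint_ul_min_pmol <- cl$clint_ul_min_pmol * factor
        hit <- TRUE
      }
    }
    if (!hit) abort(sprintf("no enzyme_mediated clearance for `%s`", enz))
  } else if (field == "renal_clearance") {
    hit <- FALSE
    for (k in seq_along(cmp$clearance)) {
      cl <- cmp$clearance[[k]]
      if (cl$kind == "renal" && (is.null(cl$species) || cl$species == species)) {
        cmp$clearance[[k]]$renal_clearance_ml_min_kg <-
          cl$renal_clearance_ml_min_kg * factor
        hit <- TRUE
      }
    }
    if (!hit) abort("no renal clearance process to perturb")
  } else if (field == "hepatic_t_half") {
    hit <- FALSE
    for (k in seq_along(cmp$clearance)) {
      cl <- cmp$clearance[[k]]
      if (cl$kind == "total_hepatic_halflife" &&
          (is.null(cl$species) || cl$species == species)) {
        cmp$clearance[[k]]$hepatic_t_half_min <- cl$hepatic_t_half_min * factor
        hit <- TRUE
      }
    }
    if (!hit) abort("no total_hepatic_halflife process to perturb")
  } else if (field == "ki") {
    enz <- parts[2]
    hit <- FALSE
    for (k in seq_along(cmp$inhibitions)) {
      inh <- cmp$inhibitions[[k]]
      if (identical(inh$enzyme, enz) &&
          (is.null(inh$species) || inh$species == species)) {
        cmp$inhibitions[[k]]$ki_um <- inh$ki_um * factor
        hit <- TRUE
      }
    }
    if (!hit) abort(sprintf("no inhibition constant for `%s`", enz))
  } else if (field %in% c("dissolution_time", "dissolution_shape")) {
    if (is.null(formulation)) abort("no formulation in scope for dissolution parameters")
    hit <- FALSE
    for (k in seq_along(cmp$formulations)) {
      f <- cmp$formulations[[k]]
      if (identical(f$name, formulation) && f$kind == "tablet") {
        fld <- if (field == "dissolution_time") "dissolution_time_min" else
          "dissolution_shape"
        cmp$formulations[[k]][[fld]] <- f[[fld]] * factor
        hit <- TRUE
      }
    }
    if (!hit) abort(sprintf("formulation `%s` is not a tablet", formulation))
  } else {
    abort(sprintf("cannot resolve compound parameter `%s`", key))
  }
  cmp
}

# multiply one addressed scalar of a scenario by `factor`; paths are
# dotted: "compound.<param>" / "victim.<param>" / "perpetrator.<param>",
# "dose" / "victim_dose" / "perpetrator_dose",
# "physiology.<override key>" (see load_physiology)
perturb_scenario <- function(sc, path, factor) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  rest <- paste(parts[-1], collapse = ".")
  if (inherits(sc, "pbpk_scenario")) {
    if (head == "compound") {
      sc$compound <- modify_compound(sc$compound, rest, factor, sc$species,
                                     sc$formulation)
    } else if (head == "dose") {
      sc$dose <- sc$dose * factor
    } else if (head == "physiology") {
      sc$physiology_overrides <-
        perturb_physiology_overrides(sc$physiology_overrides, sc$species,
                                     sc$body_weight, rest, factor)
    } else {
      abort(sprintf("cannot resolve scenario path `%s`", path))
    }
  } else if (inherits(sc, "ddi_scenario")) {
    if (head == "victim") {
      sc$victim <- modify_compound(sc$victim, rest, factor, sc$species,
                                   sc$victim_formulation)
    } else if (head == "perpetrator") {
      sc$perpetrator <- modify_compound(sc$perpetrator, rest, factor,
                                        sc$species, sc$perp_formulation)
    } else if (head == "victim_dose") {
      sc$victim_dose <- sc$victim_dose * factor
    } else if (head == "perpetrator_dose") {
      sc$perp_dose <- sc$perp_dose * factor
    } else if (head == "physiology") {
      sc$physiology_overrides <-
        perturb_physiology_overrides(sc$physiology_overrides, sc$species,
                                     sc$body_weight, rest, factor)
    } else {
      abort(sprintf("cannot resolve scenario path `%s`", path))
    }
  } else {
    abort("scenario must be a pbpk_scenario or ddi_scenario")
  }
  sc
}

# physiology overrides are absolute values: read the current effective
# value at reference weight, multiply, and store as an override
perturb_physiology_overrides <- function(overrides, species, body_weight,
                                         key, factor) {
  cur <- load_physiology(species, NULL, overrides) # reference weight
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  val <- if (length(parts) == 1) {
    switch(parts[1],
      mppgl = cur$mppgl,
      hematocrit = cur$hematocrit,
      cardiac_output_ml_min = cur$cardiac_output_ml_h / 60,
      blood_volume_ml = sum(cur$blood),
      abort(sprintf("cannot resolve physiology path `%s`", key)))
  } else if (parts[1] == "organ") {
    as.numeric(cur$organs[cur$organs$organ == parts[2], parts[3]])
  } else if (parts[1] == "gi") {
    as.numeric(cur$gi[cur$gi$segment == parts[2], parts[3]])
  } else if (parts[1] == "enzyme") {
    cur$enzymes$ref_conc_pmol_per_mg[cur$enzymes$enzyme == parts[2]]
  } else {
    abort(sprintf("cannot resolve physiology path `%s`", key))
  }
  if (!length(val) || !is.finite(val)) {
    abort(sprintf("cannot resolve physiology path `%s`", key))
  }
  overrides[[key]] <- val * factor
  overrides
}
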