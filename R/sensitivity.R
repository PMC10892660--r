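# Local one-at-a-time sensitivity analysis of model outputs.

#' Local sensitivity scan of a scenario
#'
#' For each addressed parameter `p`, perturbs it by the fraction `delta`
#' (forward difference by default, central optionally), re-simulates, and
#' reports the normalized sensitivity coefficient
#' `SC = (dPK / PK) / (dp / p)` for the victim's Cmax and AUCinf —
#' under co-administration for a [ddi_scenario()], or for the compound
#' itself for a [pbpk_scenario()]. An SC of +1 means a +10% parameter
#' change moves the output by +10%. Parameters with `|SC| > 0.1` are
#' flagged sensitive.
#'
#' @param scenario a [pbpk_scenario()] or [ddi_scenario()].
#' @param parameters character vector of parameter paths (see
#'   [perturb_scenario()] for the addressing scheme), e.g.
#'   `"victim.fraction_unbound"`, `"perpetrator.ki.CYP3A2"`,
#'   `"victim.clint.CYP3A2"`, `"physiology.enzyme.CYP3A2"`, `"dose"`.
#' @param delta relative perturbation in (0, 0.5]; default +0.10.
#' @param method `"forward"` (default) or `"central"` difference.
#' @return tibble sorted by decreasing `|SC|` (on AUCinf): `parameter`,
#'   `delta`, `sc_cmax`, `sc_aucinf`, `sensitive` (either |SC| > 0.1),
#'   plus the baseline `cmax` and `auc_inf` as attributes
#'   `baseline_cmax`, `baseline_aucinf`.
#' @export
sensitivity_scan <- function(scenario, parameters, delta = 0.1,
                             method = c("forward", "central")) {
  method <- match.arg(method)
  if (delta <= 0 || delta > 0.5) abort("`delta` must lie in (0, 0.5]")
  if (!length(parameters)) abort("`parameters` must be nonempty")

  pk_of <- function(sc) {
    prof <- scenario_profile(sc)
    nca_single(prof)
  }
  base <- pk_of(scenario)
  if (!is.finite(base$cmax) || base$cmax <= 0 ||
      !is.finite(base$auc_inf) || base$auc_inf <= 0) {
    abort("baseline simulation gives no positive Cmax/AUCinf")
  }

  rows <- purrr::map_dfr(parameters, function(p) {
    up <- pk_of(perturb_scenario(scenario, p, 1 + delta))
    if (method == "central") {
      dn <- pk_of(perturb_scenario(scenario, p, 1 - delta))
      sc_cmax <- (up$cmax - dn$cmax) / base$cmax / (2 * delta)
      sc_auc <- (up$auc_inf - dn$auc_inf) / base$auc_inf / (2 * delta)
    } else {
      sc_cmax <- (up$cmax - base$cmax) / base$cmax / delta
      sc_auc <- (up$auc_inf - base$auc_inf) / base$auc_inf / delta
    }
    tibble(parameter = p, delta = delta,
           sc_cmax = sc_cmax, sc_aucinf = sc_auc)
  })
  out <- rows |>
    mutate(sensitive = pmax(abs(.data$sc_cmax), abs(.data$sc_aucinf)) > 0.1) |>
    arrange(dplyr::desc(pmax(abs(.data$sc_aucinf), abs(.data$sc_cmax))))
  attr(out, "baseline_cmax") <- base$cmax
  attr(out, "baseline_aucinf") <- base$auc_inf
  out
}

#' Default sensitivity parameter list for a DDI scenario
#'
#' Covers the compound parameter tables of both drugs (lipophilicity,
#' fraction unbound, permeabilities, clearance constants, dissolution for
#' tablets, Ki) plus the enzyme abundance scaling factors.
#'
#' @param scenario a [ddi_scenario()].
#' @return character vector of parameter paths.
#' @export
default_sensitivity_parameters <- function(scenario) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  sp <- scenario$species
  paths <- c()
  for (side in c("victim", "perpetrator")) {
    cmp <- scenario[[side]]
    paths <- c(paths,
               paste0(side, ".lipophilicity_logd74"),
               paste0(side, ".fraction_unbound"),
               paste0(side, ".intestinal_permeability"),
               paste0(side, ".cellular_permeability"))
    for (cl in clearances_for(cmp, sp)) {
      paths <- c(paths, switch(cl$kind,
        enzyme_mediated = paste0(side, ".clint.", cl$enzyme),
        renal = paste0(side, ".renal_clearance"),
        total_hepatic_halflife = paste0(side, ".hepatic_t_half")))
    }
    for (inh in inhibitions_for(cmp, sp)) {
      paths <- c(paths, paste0(side, ".ki.", inh$enzyme))
    }
    form <- formulation_spec(cmp, scenario[[paste0(
      if (side == "victim") "victim" else "perp", "_formulation")]])
    if (identical(form$kind, "tablet")) {
      paths <- c(paths, paste0(side, ".dissolution_time"),
                 paste0(side, ".dissolution_shape"))
    }
  }
  phys <- load_physiology(sp)
  paths <- c(paths, paste0("physiology.enzyme.", phys$enzymes$enzyme),
             "physiology.mppgl")
  unique(paths)
}
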