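# Victim-perpetrator coupling: dynamic competitive inhibition of the
# victim's CYP-mediated intrinsic clearance, and the static 1 + [I]/Ki
# screening index.

#' Apparent intrinsic clearance under competitive inhibition
#'
#' `CLint_app = CLint / (1 + I / Ki)`: the victim's intrinsic clearance
#' is reduced by the unbound inhibitor concentration relative to the
#' competitive inhibition constant. Equals `CLint` without inhibitor and
#' halves at `I = Ki`.
#'
#' @param clint_ul_min_pmol uninhibited intrinsic clearance, uL/min/pmol.
#' @param i_unbound_um unbound inhibitor concentration, uM (>= 0).
#' @param ki_um competitive inhibition constant, uM (> 0).
#' @return apparent intrinsic clearance, uL/min/pmol.
#' @export
#' @examples
#' apparent_clint(1.99, 0, 0.39)     # no inhibitor: unchanged
#' apparent_clint(2, 0.39, 0.39)     # half at I = Ki
apparent_clint <- function(clint_ul_min_pmol, i_unbound_um, ki_um) {
  check_nonnegative(clint_ul_min_pmol, "clint_ul_min_pmol")
  check_nonnegative(i_unbound_um, "i_unbound_um")
  check_positive(ki_um, "ki_um")
  clint_ul_min_pmol / (1 + i_unbound_um / ki_um)
}

#' Static competitive-inhibition DDI index
#'
#' The screening index `1 + [I]/Ki` with `[I]` the unbound molar
#' perpetrator concentration derived from its plasma Cmax:
#' `[I] = Cmax * fu / MW` (ng/mL over g/mol gives uM).
#'
#' @param cmax_ng_ml perpetrator plasma Cmax, ng/mL.
#' @param fu perpetrator plasma fraction unbound.
#' @param mw_g_mol perpetrator molecular weight, g/mol.
#' @param ki_um competitive inhibition constant, uM.
#' @return dimensionless index (>= 1; 1 means no interaction predicted).
#' @export
#' @examples
#' static_index(69.3, 0.084, 479.59, 0.39)
static_index <- function(cmax_ng_ml, fu, mw_g_mol, ki_um) {
  check_positive(cmax_ng_ml, "cmax_ng_ml")
  check_positive(fu, "fu")
  check_positive(mw_g_mol, "mw_g_mol")
  check_positive(ki_um, "ki_um")
  1 + (cmax_ng_ml * fu / mw_g_mol) / ki_um
}

# inhibition specs of the perpetrator whose enzyme appears among the
# victim's enzyme-mediated clearance processes for this species
matched_inhibitions <- function(victim, perpetrator, species) {
  inh <- inhibitions_for(perpetrator, species)
  if (!length(inh)) abort("perpetrator declares no inhibition for this species")
  victim_enzymes <- vapply(
    Filter(function(cl) cl$kind == "enzyme_mediated",
           clearances_for(victim, species)),
    `[[`, character(1), "enzyme")
  matched <- vapply(inh, function(x) x$enzyme %in% victim_enzymes, logical(1))
  if (!any(matched)) {
    abort("none of the perpetrator's inhibited enzymes appears in a victim clearance process")
  }
  inh[matched]
}

#' Describe a victim-perpetrator co-administration scenario
#'
#' @param victim,perpetrator [compound()] objects; the perpetrator must
#'   declare competitive inhibition constants whose enzymes appear among
#'   the victim's enzyme-mediated clearance processes for this species.
#' @param species `"rat"` or `"human"`.
#' @param victim_dose,perp_dose doses (mg/kg if `per_kg`, else mg);
#'   `perp_dose = 0` simulates the victim alone in the coupled system.
#' @param per_kg interpret doses per kg body weight.
#' @param victim_formulation,perp_formulation formulation names.
#' @param route administration route for both drugs.
#' @param body_weight kg; bundled reference weight when `NULL`.
#' @param duration_h simulated time span.
#' @param dose_times_h administration times for both drugs.
#' @param inhibitor_source where the inhibitor concentration driving
#'   Eq.-type competitive inhibition is read:
#'   `"liver_intracellular_unbound"` (default; for a gut-wall enzyme the
#'   perpetrator's gut intracellular unbound concentration is used — the
#'   enzyme's own compartment) or `"plasma_unbound"` (venous plasma).
#' @param physiology_overrides,engine_options,solver as in
#'   [pbpk_scenario()].
#' @return an object of class `ddi_scenario`.
#' @export
ddi_scenario <- function(victim, perpetrator, species,
                         victim_dose, perp_dose, per_kg = TRUE,
                         victim_formulation = "solution",
                         perp_formulation = "solution",
                         route = "oral", body_weight = NULL,
                         duration_h = 24, dose_times_h = 0,
                         inhibitor_source = c("liver_intracellular_unbound",
                                              "plasma_unbound"),
                         physiology_overrides = list(),
                         engine_options = list(), solver = list()) {
  stopifnot(inherits(victim, "pbpk_compound"),
            inherits(perpetrator, "pbpk_compound"))
  inhibitor_source <- match.arg(inhibitor_source)
  check_nonnegative(c(victim_dose, perp_dose), "doses")
  inh <- matched_inhibitions(victim, perpetrator, species)
  structure(list(
    victim = victim, perpetrator = perpetrator, species = species,
    victim_dose = victim_dose, perp_dose = perp_dose, per_kg = per_kg,
    victim_formulation = victim_formulation,
    perp_formulation = perp_formulation,
    route = route, body_weight = body_weight, duration_h = duration_h,
    dose_times_h = dose_times_h,
    inhibitions = inh,
    inhibitor_source = inhibitor_source,
    physiology_overrides = physiology_overrides,
    engine_options = engine_options, solver = solver
  ), class = "ddi_scenario")
}

#' @export
print.ddi_scenario <- function(x, ...) {
  cat(sprintf("<ddi_scenario> %s (%g %s) + %s (%g %s), %s, %s\n",
              x$victim$name, x$victim_dose, if (x$per_kg) "mg/kg" else "mg",
              x$perpetrator$name, x$perp_dose, if (x$per_kg) "mg/kg" else "mg",
              x$species, x$inhibitor_source))
  invisible(x)
}

#' Co-simulate a victim-perpetrator DDI scenario
#'
#' Simulates the victim alone and both compounds together in one coupled
#' ODE system. At every solver step the victim's enzyme-mediated
#' intrinsic clearance is replaced by [apparent_clint()] using the
#' perpetrator's current unbound concentration at the configured source.
#' PK parameters for both arms come from [nca_single()] on the simulated
#' venous plasma profiles, and the DDI AUCinf and Cmax ratios from
#' [ddi_ratios()].
#'
#' @param scenario a [ddi_scenario()].
#' @return an object of class `ddi_result` with elements `alone_profile`,
#'   `combo_profile`, `perp_profile`, `pk_alone`, `pk_combo`, `ratios`,
#'   `alone_sim`, `combo_states`, `scenario`.
#' @export
simulate_ddi <- function(scenario) {
  stopifnot(inherits(scenario, "ddi_scenario"))
  sc <- scenario
  phys <- load_physiology(sc$species, sc$body_weight,
                          sc$physiology_overrides)
  mv <- build_model(sc$victim, phys, options = sc$engine_options)
  mp <- build_model(sc$perpetrator, phys, options = sc$engine_options)
  sv <- utils::modifyList(SOLVER_DEFAULTS, sc$solver)

  vic_sc <- pbpk_scenario(sc$victim, sc$species, sc$victim_dose,
                          per_kg = sc$per_kg, route = sc$route,
                          formulation = sc$victim_formulation,
                          body_weight = sc$body_weight,
                          duration_h = sc$duration_h,
                          dose_times_h = sc$dose_times_h,
                          physiology_overrides = sc$physiology_overrides,
                          engine_options = sc$engine_options,
                          solver = sc$solver)
  doses_v <- scenario_doses(vic_sc, sc$victim, sc$victim_dose,
                            sc$victim_formulation, sc$route)
  doses_p <- scenario_doses(vic_sc, sc$perpetrator, sc$perp_dose,
                            sc$perp_formulation, sc$route)

  alone <- simulate_pbpk(mv, doses_v, sc$duration_h, sc$solver)

  # coupled system: victim block first, perpetrator block offset
  nsv <- mv$n_states
  times <- seq(0, sc$duration_h, by = sv$dt_out)
  bv <- if (nrow(doses_v)) dose_events_for(mv, doses_v, offset = 0L) else NULL
  bp <- if (nrow(doses_p)) dose_events_for(mp, doses_p, offset = nsv) else NULL
  events <- dplyr::bind_rows(if (!is.null(bv)) bv$events,
                             if (!is.null(bp)) bp$events)
  if (!is.null(events) && nrow(events)) {
    times <- sort(unique(c(times, events$time)))
  } else {
    events <- NULL
  }

  # inhibition bookkeeping per victim metabolism route; resolved from the
  # scenario's current compounds so parameter perturbations are honored
  inh_now <- matched_inhibitions(sc$victim, sc$perpetrator, sc$species)
  ki_by_enzyme <- stats::setNames(
    vapply(inh_now, `[[`, numeric(1), "ki_um"),
    vapply(inh_now, `[[`, character(1), "enzyme"))
  routes_v <- mv$routes
  rv_coef <- vapply(routes_v, `[[`, numeric(1), "coef")
  rv_cell <- vapply(routes_v, `[[`, integer(1), "cell_idx")
  rv_ki <- vapply(routes_v, function(r) {
    unname(ki_by_enzyme[r$enzyme]) %||% NA_real_
  }, numeric(1))
  # perpetrator state index + scale giving Cu (uM) at the inhibitor source
  rv_src_idx <- integer(length(routes_v))
  rv_src_scale <- numeric(length(routes_v))
  for (k in seq_along(routes_v)) {
    if (sc$inhibitor_source == "plasma_unbound") {
      rv_src_idx[k] <- nsv + mp$i_ven_pl
      rv_src_scale[k] <- mp$fu / mp$v$ven_pl
    } else {
      i <- match(routes_v[[k]]$organ, mp$physiology$organs$organ)
      rv_src_idx[k] <- nsv + mp$idx$cell[i]
      rv_src_scale[k] <- mp$fu / (mp$kp[i] * mp$v$cell[i])
    }
  }
  routes_p <- mp$routes
  rp_coef <- vapply(routes_p, `[[`, numeric(1), "coef")
  rp_cell <- nsv + vapply(routes_p, `[[`, integer(1), "cell_idx")

  Mv <- mv$M; Mp <- mp$M
  iv_met <- mv$i_met; ip_met <- nsv + mp$i_met
  idx_v <- seq_len(nsv)
  idx_p <- nsv + seq_len(mp$n_states)

  deriv <- function(t, y, parms) {
    yv <- y[idx_v]; yp <- y[idx_p]
    dy <- c(as.vector(Mv %*% yv), as.vector(Mp %*% yp))
    if (length(rv_coef)) {
      fac <- rep(1, length(rv_coef))
      hit <- !is.na(rv_ki)
      if (any(hit)) {
        cu <- pmax(y[rv_src_idx[hit]], 0) * rv_src_scale[hit]
        fac[hit] <- 1 / (1 + cu / rv_ki[hit])
      }
      f <- rv_coef * fac * y[rv_cell]
      dy[rv_cell] <- dy[rv_cell] - f
      dy[iv_met] <- dy[iv_met] + sum(f)
    }
    if (length(rp_coef)) {
      f <- rp_coef * y[rp_cell]
      dy[rp_cell] <- dy[rp_cell] - f
      dy[ip_met] <- dy[ip_met] + sum(f)
    }
    dy[idx_v] <- apply_dissolution(dy[idx_v], yv, t, mv, bv)
    dy[idx_p] <- apply_dissolution(dy[idx_p], yp, t, mp, bp)
    list(dy)
  }

  y0 <- stats::setNames(rep(0, nsv + mp$n_states),
                        seq_len(nsv + mp$n_states))
  out <- deSolve::lsoda(
    y = y0, times = times, func = deriv, parms = NULL,
    rtol = sv$rtol, atol = sv$atol, maxsteps = sv$maxsteps,
    events = if (!is.null(events)) list(data = as.data.frame(events)) else NULL)
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("coupled DDI solve failed (istate %d)",
                  attr(out, "istate")[1]))
  }
  tt <- out[, 1]
  states <- unname(out[, -1, drop = FALSE])

  combo_profile <- tibble(
    time_h = tt,
    conc_ng_per_ml = states[, mv$i_ven_pl] / mv$v$ven_pl *
      sc$victim$molecular_weight)
  perp_profile <- tibble(
    time_h = tt,
    conc_ng_per_ml = states[, nsv + mp$i_ven_pl] / mp$v$ven_pl *
      sc$perpetrator$molecular_weight)

  pk_alone <- nca_single(alone$profile, dose = sc$victim_dose,
                         dose_per_kg = sc$per_kg)
  pk_combo <- nca_single(combo_profile, dose = sc$victim_dose,
                         dose_per_kg = sc$per_kg)
  ratios <- ddi_ratios(pk_alone, pk_combo)

  structure(list(
    alone_profile = alone$profile,
    combo_profile = combo_profile,
    perp_profile = perp_profile,
    pk_alone = pk_alone, pk_combo = pk_combo,
    ratios = ratios,
    alone_sim = alone,
    combo_states = states, combo_time_h = tt,
    victim_model = mv, perp_model = mp,
    scenario = sc
  ), class = "ddi_result")
}

#' @export
print.ddi_result <- function(x, ...) {
  cat(sprintf("<ddi_result> %s + %s (%s)\n", x$scenario$victim$name,
              x$scenario$perpetrator$name, x$scenario$species))
  cat(sprintf("  DDI AUCinf ratio %.3f, Cmax ratio %.3f\n",
              x$ratios$ddi_auc_ratio, x$ratios$ddi_cmax_ratio))
  invisible(x)
}

#' Tidy a DDI co-simulation result
#'
#' @param x a `ddi_result`.
#' @param ... unused.
#' @return tibble of victim PK parameters for both arms plus the ratios.
#' @export
tidy.ddi_result <- function(x, ...) {
  bind_rows(
    mutate(x$pk_alone, arm = "victim_alone", .before = 1),
    mutate(x$pk_combo, arm = "victim_coadministered", .before = 1))
}

#' @export
glance.ddi_result <- function(x, ...) {
  tibble(ddi_auc_ratio = x$ratios$ddi_auc_ratio,
         ddi_cmax_ratio = x$ratios$ddi_cmax_ratio,
         victim = x$scenario$victim$name,
         perpetrator = x$scenario$perpetrator$name,
         species = x$scenario$species)
}
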