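# Whole-body permeability-limited PBPK engine.
#
# Internal units: time h, volume mL, amount nmol, concentration nmol/mL
# (= uM). Each organ carries 4 sub-compartments (vascular plasma, blood
# cells, interstitial, intracellular) exchanging along unbound-concentration
# gradients; organs are connected by blood flow through arterial and venous
# pools with the lung in series, and the liver receives hepatic-arterial
# plus portal (gut + spleen) inflow. The gut lumen is a stomach + 3
# small-intestine transit chain with Weibull dissolution and
# permeability-limited absorption into the gut wall.

ENGINE_DEFAULTS <- list(
  k_endo_per_h = 1000,    # plasma<->interstitial exchange, 1/h per mL organ
  a_cell_cm2_per_ml = 3000, # cell surface area per mL cellular space
  k_rbc_per_h = 500,      # plasma<->blood-cell exchange, 1/h per mL cells
  perm_cap_per_h = 1e5,   # cap on any exchange rate constant
  dissolution_cap_per_h = 500
)

SOLVER_DEFAULTS <- list(rtol = 1e-8, atol = 1e-10, dt_out = 0.01,
                        maxsteps = 5e5)

#' Assemble the PBPK ODE system for one compound
#'
#' Builds the state layout, the constant-coefficient transport matrix
#' (blood flows, sub-compartment permeability exchange, gut transit and
#' absorption, renal clearance, hepatic half-life elimination) and the
#' enzyme-mediated metabolism routes for a compound in a physiology.
#'
#' @param cmp a [compound()].
#' @param phys a [load_physiology()] object.
#' @param kps partition coefficients as from [partition_coefficients()];
#'   computed automatically when `NULL`.
#' @param options engine options overriding the defaults
#'   (`k_endo_per_h`, `a_cell_cm2_per_ml`, `k_rbc_per_h`,
#'   `perm_cap_per_h`).
#' @return an object of class `pbpk_model`.
#' @export
build_model <- function(cmp, phys, kps = NULL, options = list()) {
  stopifnot(inherits(cmp, "pbpk_compound"), inherits(phys, "pbpk_physiology"))
  opt <- utils::modifyList(ENGINE_DEFAULTS, options)
  if (is.null(kps)) kps <- partition_coefficients(cmp, phys)
  org <- phys$organs
  n <- nrow(org)
  if (!all(org$organ %in% kps$organ)) abort("missing Kp for at least one organ")
  kp <- kps$kp[match(org$organ, kps$organ)]

  hct <- phys$hematocrit
  fu <- fu_plasma(cmp, phys$species)
  kp_rbc <- kp_erythrocyte(cmp)

  v_pl <- org$volume_ml * org$f_vascular * (1 - hct)
  v_rbc <- org$volume_ml * org$f_vascular * hct
  v_is <- org$volume_ml * org$f_interstitial
  v_cell <- org$volume_ml * (1 - org$f_vascular - org$f_interstitial)
  q <- org$flow_ml_h
  q_pl <- q * (1 - hct)
  q_rbc <- q * hct

  i_lung <- which(org$organ == "lung")
  i_liver <- which(org$organ == "liver")
  i_gut <- which(org$organ == "gut")
  i_spleen <- which(org$organ == "spleen")
  if (length(i_lung) != 1 || length(i_liver) != 1) {
    abort("physiology must contain exactly one lung and one liver")
  }
  portal <- c(i_gut, i_spleen)

  # liver throughput = hepatic artery + portal inflow
  q_liv_out_pl <- q_pl[i_liver] + sum(q_pl[portal])
  q_liv_out_rbc <- q_rbc[i_liver] + sum(q_rbc[portal])

  # state layout
  idx <- list(pl = 1:n, rbc = as.integer(n + 1:n),
              is = as.integer(2 * n + 1:n), cell = as.integer(3 * n + 1:n))
  i_art_pl <- 4 * n + 1; i_art_rbc <- 4 * n + 2
  i_ven_pl <- 4 * n + 3; i_ven_rbc <- 4 * n + 4
  gi <- phys$gi
  stopifnot(identical(gi$segment, c("stomach", "si1", "si2", "si3")))
  i_lum_u <- 4 * n + 4 + c(1, 3, 5, 7)
  i_lum_d <- 4 * n + 4 + c(2, 4, 6, 8)
  i_met <- 4 * n + 13; i_urine <- 4 * n + 14
  i_hep <- 4 * n + 15; i_feces <- 4 * n + 16
  ns <- 4 * n + 16
  state_names <- c(paste0("pl_", org$organ), paste0("rbc_", org$organ),
                   paste0("is_", org$organ), paste0("cell_", org$organ),
                   "arterial_plasma", "arterial_rbc",
                   "venous_plasma", "venous_rbc",
                   paste0(rep(gi$segment, each = 2), c("_undissolved", "_dissolved")),
                   "metabolized", "urine", "hepatic_eliminated", "feces")

  v_art_pl <- phys$blood[["arterial_plasma"]]
  v_art_rbc <- phys$blood[["arterial_rbc"]]
  v_ven_pl <- phys$blood[["venous_plasma"]]
  v_ven_rbc <- phys$blood[["venous_rbc"]]

  M <- matrix(0, ns, ns)
  add <- function(i, j, rate) M[i, j] <<- M[i, j] + rate
  move <- function(from, to, rate) { # first-order transfer from -> to
    add(from, from, -rate); add(to, from, rate)
  }

  co_pl <- sum(q_pl[-i_lung]); co_rbc <- sum(q_rbc[-i_lung])

  # circulation: venous -> lung -> arterial -> organs -> venous
  move(i_ven_pl, idx$pl[i_lung], co_pl / v_ven_pl)
  move(i_ven_rbc, idx$rbc[i_lung], co_rbc / v_ven_rbc)
  move(idx$pl[i_lung], i_art_pl, co_pl / v_pl[i_lung])
  move(idx$rbc[i_lung], i_art_rbc, co_rbc / v_rbc[i_lung])
  for (i in seq_len(n)) {
    if (i == i_lung) next
    move(i_art_pl, idx$pl[i], q_pl[i] / v_art_pl)
    move(i_art_rbc, idx$rbc[i], q_rbc[i] / v_art_rbc)
    if (i %in% portal) { # splanchnic outflow feeds the liver
      move(idx$pl[i], idx$pl[i_liver], q_pl[i] / v_pl[i])
      move(idx$rbc[i], idx$rbc[i_liver], q_rbc[i] / v_rbc[i])
    } else if (i == i_liver) {
      move(idx$pl[i], i_ven_pl, q_liv_out_pl / v_pl[i])
      move(idx$rbc[i], i_ven_rbc, q_liv_out_rbc / v_rbc[i])
    } else {
      move(idx$pl[i], i_ven_pl, q_pl[i] / v_pl[i])
      move(idx$rbc[i], i_ven_rbc, q_rbc[i] / v_rbc[i])
    }
  }

  # sub-compartment exchange along unbound-concentration gradients:
  # flux = ps * (Cu_1 - Cu_2) with Cu = A / (v * k); for a plasma-like
  # space k = 1/fu, for a partitioned space k = Kp/fu (so that at
  # equilibrium C_total ratio equals Kp)
  p_cell_cm_h <- cellular_permeability_cm_h(cmp)
  exch <- function(i1, v1, k1, i2, v2, k2, ps) {
    add(i1, i1, -ps / (v1 * k1)); add(i2, i1, ps / (v1 * k1))
    add(i2, i2, -ps / (v2 * k2)); add(i1, i2, ps / (v2 * k2))
  }
  # The endothelial and erythrocyte PS products are binding-compensated
  # (divided by fu): the fenestrated capillary endothelium and the red
  # cell membrane equilibrate small molecules fast regardless of plasma
  # protein binding, so these steps are non-limiting by default. The
  # cellular membrane keeps the compound's own permeability and is the
  # permeability-limited step.
  cap <- opt$perm_cap_per_h
  kfu <- 1 / fu
  for (i in seq_len(n)) {
    ps_endo <- min(opt$k_endo_per_h, cap) * org$volume_ml[i] / fu
    ps_rbc <- min(opt$k_rbc_per_h, cap) * v_rbc[i] / fu
    ps_cell <- min(p_cell_cm_h * opt$a_cell_cm2_per_ml, cap) * v_cell[i]
    exch(idx$pl[i], v_pl[i], kfu, idx$is[i], v_is[i], kfu, ps_endo)
    exch(idx$pl[i], v_pl[i], kfu, idx$rbc[i], v_rbc[i], kp_rbc / fu, ps_rbc)
    exch(idx$is[i], v_is[i], kfu, idx$cell[i], v_cell[i], kp[i] / fu, ps_cell)
  }
  # blood pools exchange plasma <-> cells too
  exch(i_art_pl, v_art_pl, kfu, i_art_rbc, v_art_rbc, kp_rbc / fu,
       min(opt$k_rbc_per_h, cap) * v_art_rbc / fu)
  exch(i_ven_pl, v_ven_pl, kfu, i_ven_rbc, v_ven_rbc, kp_rbc / fu,
       min(opt$k_rbc_per_h, cap) * v_ven_rbc / fu)

  # gut lumen transit, absorption
  peff_cm_h <- cmp$peff_1e6_cm_s * 1e-6 * 3600
  k_transit <- gi$transit_rate_per_h
  move(i_lum_u[1], i_lum_u[2], k_transit[1])
  move(i_lum_d[1], i_lum_d[2], k_transit[1])
  for (j in 2:4) {
    k_abs <- peff_cm_h * gi$surface_area_cm2[j] / gi$lumen_volume_ml[j]
    to_u <- if (j < 4) i_lum_u[j + 1] else i_feces
    to_d <- if (j < 4) i_lum_d[j + 1] else i_feces
    move(i_lum_u[j], to_u, k_transit[j])
    move(i_lum_d[j], to_d, k_transit[j])
    move(i_lum_d[j], idx$cell[i_gut], k_abs)
  }

  # renal clearance: plasma clearance applied to the kidney's arterial
  # plasma inflow (mechanism-agnostic; allows net secretion above GFR*fu)
  for (cl in clearances_for(cmp, phys$species)) {
    if (cl$kind == "renal") {
      clr_ml_h <- cl$renal_clearance_ml_min_kg * phys$body_weight * 60
      move(i_art_pl, i_urine, clr_ml_h / v_art_pl)
    }
    if (cl$kind == "total_hepatic_halflife") {
      k_hep <- log(2) / (cl$hepatic_t_half_min / 60)
      move(idx$cell[i_liver], i_hep, k_hep)
    }
  }

  # enzyme-mediated metabolism routes (kept out of M so competitive
  # inhibition can rescale them at solve time)
  routes <- list()
  for (cl in clearances_for(cmp, phys$species)) {
    if (cl$kind != "enzyme_mediated") next
    for (i in seq_len(n)) {
      if (org$cyp3a_expr[i] <= 0) next
      abundance <- organ_enzyme_abundance(phys, cl$enzyme, org$organ[i])
      if (abundance <= 0) next
      cl_ml_h <- cl$clint_ul_min_pmol * abundance * 60 / 1000
      # flux (nmol/h) = cl_ml_h * Cu_cell; Cu_cell = A_cell*fu/(Kp*V_cell)
      routes[[length(routes) + 1]] <- list(
        enzyme = cl$enzyme, organ = org$organ[i],
        cell_idx = idx$cell[i],
        coef = cl_ml_h * fu / (kp[i] * v_cell[i]),
        clint_ul_min_pmol = cl$clint_ul_min_pmol,
        abundance_pmol = abundance)
    }
  }

  structure(list(
    compound = cmp, physiology = phys, kps = kps, options = opt,
    n_organs = n, state_names = state_names, n_states = ns,
    M = M, idx = idx,
    i_art_pl = i_art_pl, i_art_rbc = i_art_rbc,
    i_ven_pl = i_ven_pl, i_ven_rbc = i_ven_rbc,
    i_lum_u = i_lum_u, i_lum_d = i_lum_d,
    i_met = i_met, i_urine = i_urine, i_hep = i_hep, i_feces = i_feces,
    v = list(pl = v_pl, rbc = v_rbc, is = v_is, cell = v_cell,
             art_pl = v_art_pl, art_rbc = v_art_rbc,
             ven_pl = v_ven_pl, ven_rbc = v_ven_rbc),
    kp = kp, kp_rbc = kp_rbc, fu = fu,
    routes = routes
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s in %s (%.3g kg): %d states, %d metabolism route(s)\n",
              x$compound$name, x$physiology$species,
              x$physiology$body_weight, x$n_states, length(x$routes)))
  invisible(x)
}

#' Construct a dose event
#'
#' @param route `"oral"` or `"iv_bolus"`.
#' @param amount dose amount (> 0), mg or mg/kg.
#' @param per_kg is `amount` per kg body weight?
#' @param time_h administration time, h (>= 0).
#' @param formulation formulation name (oral only) defined on the compound.
#' @return a one-row tibble.
#' @export
dose_event <- function(route = c("oral", "iv_bolus"), amount, per_kg = TRUE,
                       time_h = 0, formulation = "solution") {
  route <- match.arg(route)
  check_positive(amount, "amount")
  check_nonnegative(time_h, "time_h")
  tibble(route = route, amount = amount, per_kg = per_kg,
         time_h = time_h, formulation = formulation)
}

dose_amount_nmol <- function(doses, cmp, body_weight) {
  mg <- ifelse(doses$per_kg, doses$amount * body_weight, doses$amount)
  mg_to_nmol(mg, cmp$molecular_weight)
}

# build deSolve events + the oral tablet hazard closure for one model block
dose_events_for <- function(model, doses, offset = 0L) {
  cmp <- model$compound
  bw <- model$physiology$body_weight
  amounts <- dose_amount_nmol(doses, cmp, bw)
  var_idx <- integer(nrow(doses))
  tablet_form <- NULL
  oral_times <- numeric()
  for (k in seq_len(nrow(doses))) {
    if (doses$route[k] == "iv_bolus") {
      var_idx[k] <- model$i_ven_pl
    } else {
      form <- formulation_spec(cmp, doses$formulation[k])
      if (form$kind == "solution") {
        var_idx[k] <- model$i_lum_d[1]
      } else {
        var_idx[k] <- model$i_lum_u[1]
        tablet_form <- form
      }
      oral_times <- c(oral_times, doses$time_h[k])
    }
  }
  list(events = data.frame(var = var_idx + offset, time = doses$time_h,
                           value = amounts, method = "add"),
       tablet_form = tablet_form, oral_times = sort(oral_times))
}

# time-dependent dissolution contribution for a model block
apply_dissolution <- function(dy, y, t, model, block, offset = 0L) {
  if (is.null(block$tablet_form)) return(dy)
  prev <- block$oral_times[block$oral_times <= t + 1e-12]
  if (!length(prev)) return(dy)
  haz <- dissolution_hazard_per_h(block$tablet_form, t - max(prev),
                                  cap = model$options$dissolution_cap_per_h)
  u <- model$i_lum_u + offset
  d <- model$i_lum_d + offset
  f <- haz * y[u]
  dy[u] <- dy[u] - f
  dy[d] <- dy[d] + f
  dy
}

#' Simulate a PBPK model
#'
#' Integrates the whole-body system with a stiff implicit solver (lsoda)
#' on a fixed output grid, applying the dose events, Weibull tablet
#' dissolution and enzyme-mediated metabolism. Deterministic.
#'
#' @param model a [build_model()] object.
#' @param doses tibble of [dose_event()] rows (zero rows allowed).
#' @param duration_h simulation length, h; must cover all dose times.
#' @param solver list overriding `rtol` (1e-8), `atol` (1e-10 nmol),
#'   `dt_out` (0.01 h output grid), `maxsteps`.
#' @return an object of class `pbpk_sim` with elements `time_h`, `states`
#'   (matrix time x state, nmol), `profile` (tibble `time_h`,
#'   `conc_ng_per_ml` of venous plasma), `doses`, `model`, `metadata`.
#' @export
simulate_pbpk <- function(model, doses, duration_h, solver = list()) {
  stopifnot(inherits(model, "pbpk_model"))
  sv <- utils::modifyList(SOLVER_DEFAULTS, solver)
  check_positive(c(sv$rtol, sv$atol, sv$dt_out), "solver tolerances")
  if (nrow(doses) && any(doses$time_h > duration_h)) {
    abort("duration_h must cover all dose times")
  }
  times <- seq(0, duration_h, by = sv$dt_out)
  block <- NULL
  events <- NULL
  if (nrow(doses)) {
    block <- dose_events_for(model, doses)
    events <- block$events
    times <- sort(unique(c(times, events$time)))
  }

  routes <- model$routes
  r_coef <- vapply(routes, `[[`, numeric(1), "coef")
  r_cell <- vapply(routes, `[[`, integer(1), "cell_idx")
  M <- model$M
  i_met <- model$i_met

  deriv <- function(t, y, parms) {
    dy <- as.vector(M %*% y)
    if (length(r_coef)) {
      f <- r_coef * y[r_cell]
      dy[r_cell] <- dy[r_cell] - f
      dy[i_met] <- dy[i_met] + sum(f)
    }
    dy <- apply_dissolution(dy, y, t, model, block)
    list(dy)
  }

  y0 <- stats::setNames(rep(0, model$n_states), seq_len(model$n_states))
  out <- deSolve::lsoda(
    y = y0, times = times, func = deriv, parms = NULL,
    rtol = sv$rtol, atol = sv$atol, maxsteps = sv$maxsteps,
    events = if (!is.null(events)) list(data = events) else NULL)
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf("ODE solver failed for %s (istate %d); try tighter tolerances or more steps",
                  model$compound$name, attr(out, "istate")[1]))
  }
  states <- unname(out[, -1, drop = FALSE])
  colnames(states) <- model$state_names
  neg <- min(states)
  if (neg < -(1e-6 * max(states, 1))) {
    abort(sprintf("negative state excursion beyond tolerance (%.3g nmol)", neg))
  }
  tt <- out[, 1]
  conc <- states[, "venous_plasma"] / model$v$ven_pl *
    model$compound$molecular_weight
  structure(list(
    time_h = tt,
    states = states,
    profile = tibble(time_h = tt, conc_ng_per_ml = conc),
    doses = doses,
    model = model,
    metadata = list(solver = sv, compound = model$compound$name,
                    species = model$physiology$species,
                    body_weight = model$physiology$body_weight)
  ), class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s, %s: %d timepoints over %.3g h, Cmax %.4g ng/mL\n",
              x$metadata$compound, x$metadata$species, length(x$time_h),
              max(x$time_h), max(x$profile$conc_ng_per_ml)))
  invisible(x)
}

#' Tidy the state trajectories of a simulation
#'
#' @param x a `pbpk_sim`.
#' @param ... unused.
#' @return long tibble `time_h`, `compartment`, `amount_nmol`.
#' @export
tidy.pbpk_sim <- function(x, ...) {
  as_tibble(as.data.frame(x$states)) |>
    mutate(time_h = x$time_h, .before = 1) |>
    tidyr::pivot_longer(-"time_h", names_to = "compartment",
                        values_to = "amount_nmol")
}

#' One-line summary of a simulation
#' @param x a `pbpk_sim`.
#' @param ... unused.
#' @return one-row tibble with exposure summaries and mass-balance error.
#' @export
glance.pbpk_sim <- function(x, ...) {
  mb <- mass_balance(x)
  tibble(cmax_ng_per_ml = max(x$profile$conc_ng_per_ml),
         tmax_h = x$profile$time_h[which.max(x$profile$conc_ng_per_ml)],
         duration_h = max(x$time_h),
         max_mass_balance_error = max(mb$rel_error))
}

#' Mass balance of a simulation
#'
#' At every output time, compares total drug in all compartments plus the
#' cumulative elimination and unabsorbed bins with the cumulative
#' administered dose.
#'
#' @param sim a `pbpk_sim`.
#' @return tibble `time_h`, `in_system_nmol`, `administered_nmol`,
#'   `rel_error` (0 where nothing has been administered).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  total <- rowSums(sim$states)
  given <- rep(0, length(sim$time_h))
  if (nrow(sim$doses)) {
    amt <- dose_amount_nmol(sim$doses, sim$model$compound,
                            sim$model$physiology$body_weight)
    # the output row at a dose time reports the pre-event state
    for (k in seq_along(amt)) {
      given <- given + ifelse(sim$time_h > sim$doses$time_h[k] + 1e-12,
                              amt[k], 0)
    }
  }
  rel <- ifelse(given > 0, abs(total - given) / given, abs(total))
  tibble(time_h = sim$time_h, in_system_nmol = total,
         administered_nmol = given, rel_error = rel)
}

#' First-order enzyme-mediated metabolic flux
#'
#' `flux = CLint_app * abundance * Cu / 1000`: intrinsic clearance per
#' pmol enzyme (uL/min/pmol) times enzyme amount (pmol) gives a clearance
#' in uL/min; applied to the unbound intracellular concentration (uM =
#' nmol/mL) it yields nmol/min.
#'
#' @param clint_app_ul_min_pmol apparent intrinsic clearance, uL/min/pmol.
#' @param abundance_pmol enzyme amount, pmol.
#' @param unbound_conc_um unbound intracellular concentration, uM.
#' @return metabolic flux, nmol/min.
#' @export
#' @examples
#' metabolism_flux(1.99, 45248, 1) # ~90 nmol/min
metabolism_flux <- function(clint_app_ul_min_pmol, abundance_pmol,
                            unbound_conc_um) {
  check_nonnegative(clint_app_ul_min_pmol, "clint_app_ul_min_pmol")
  check_nonnegative(abundance_pmol, "abundance_pmol")
  check_nonnegative(unbound_conc_um, "unbound_conc_um")
  clint_app_ul_min_pmol * abundance_pmol * unbound_conc_um / 1000
}

# unbound concentration (uM) in a sub-compartment of a sim state row/matrix
unbound_conc <- function(model, states, compartment, organ) {
  i <- match(organ, model$physiology$organs$organ)
  if (is.na(i)) abort(sprintf("unknown organ `%s`", organ))
  switch(compartment,
    plasma = states[, model$idx$pl[i]] / model$v$pl[i] * model$fu,
    interstitial = states[, model$idx$is[i]] / model$v$is[i] * model$fu,
    intracellular = states[, model$idx$cell[i]] / model$v$cell[i] *
      model$fu / model$kp[i],
    abort("compartment must be plasma, interstitial or intracellular"))
}
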