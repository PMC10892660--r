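#' Intrinsic clearance from a substrate-depletion half-life
#'
#' Scales the first-order depletion rate observed in a recombinant-CYP
#' incubation to intrinsic clearance per pmol of enzyme:
#' `CLint = (ln 2 / t_half) * 1000 / enzyme_conc`, i.e. the rate constant
#' (1/min) times the incubation volume containing one pmol of CYP (uL).
#'
#' @param t_half_min depletion half-life, minutes.
#' @param enzyme_conc_pmol_ml enzyme concentration in the incubation,
#'   pmol CYP/mL.
#' @return intrinsic clearance, uL/min/pmol CYP.
#' @export
#' @examples
#' clint_from_halflife(34.8, 10) # ~1.99
clint_from_halflife <- function(t_half_min, enzyme_conc_pmol_ml) {
  check_positive(t_half_min, "t_half_min")
  check_positive(enzyme_conc_pmol_ml, "enzyme_conc_pmol_ml")
  (log(2) / t_half_min) * 1000 / enzyme_conc_pmol_ml
}

#' Fit a substrate-depletion time course
#'
#' Log-linear least squares of the remaining fraction against incubation
#' time; the depletion half-life is `ln 2` over the magnitude of the
#' fitted slope. Non-decaying data (slope >= 0) are rejected.
#'
#' @param data data frame with columns `time_min` and `fraction_remaining`
#'   (replicates as repeated rows; an optional `replicate` column is
#'   ignored by the fit).
#' @param exclude_t0 drop the t = 0 normalization point before fitting.
#' @return an object of class `depletion_fit` with elements `t_half_min`,
#'   `k_per_min`, `r_squared`, `n`, and the underlying `lm` fit;
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
#' @examples
#' d <- data.frame(time_min = c(0, 5, 10, 20, 30),
#'                 fraction_remaining = exp(-log(2) / 34.8 * c(0, 5, 10, 20, 30)))
#' fit_depletion(d)$t_half_min
fit_depletion <- function(data, exclude_t0 = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("time_min", "fraction_remaining") %in% names(data)))
  d <- as_tibble(data)
  if (exclude_t0) d <- d[d$time_min > 0, ]
  if (length(unique(d$time_min)) < 3) {
    abort("need at least 3 distinct timepoints to fit a depletion curve")
  }
  if (any(d$fraction_remaining <= 0)) {
    abort("fraction_remaining must be positive for log-linear fitting")
  }
  fit <- stats::lm(log(fraction_remaining) ~ time_min, data = d)
  slope <- stats::coef(fit)[["time_min"]]
  if (slope >= 0) {
    abort("no measurable depletion: remaining fraction does not decline")
  }
  structure(list(
    t_half_min = log(2) / abs(slope),
    k_per_min = abs(slope),
    # noiseless synthetic data legitimately fit perfectly
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = nrow(d),
    fit = fit
  ), class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("<depletion_fit> t1/2 = %.3g min (k = %.3g /min, R2 = %.4f, n = %d)\n",
              x$t_half_min, x$k_per_min, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.depletion_fit <- function(x, ...) {
  tibble(term = c("t_half_min", "k_per_min"),
         estimate = c(x$t_half_min, x$k_per_min))
}

#' @export
glance.depletion_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n)
}

#' Fit an IC50 inhibition curve
#'
#' Nonlinear least-squares fit of metabolite formation (% of the
#' uninhibited control) against inhibitor concentration with the Hill
#' model `response = bottom + (top - bottom) / (1 + (I / IC50)^h)`.
#' By default the asymptotes are fixed (top 100%, bottom 0%) and the Hill
#' slope floats, which keeps the fit identifiable on a 9-concentration
#' design; `floating = TRUE` releases both asymptotes.
#'
#' @param data data frame with columns `inhibitor_uM` (including the 0
#'   control) and `pct_control`.
#' @param floating release top/bottom instead of fixing them at 100/0.
#' @return an object of class `ic50_fit` with `ic50_um`, `hill_slope`,
#'   `r_squared`, `top`, `bottom`, `floating`, and the `nls` fit;
#'   `tidy()`/`glance()` methods are provided.
#' @export
#' @examples
#' conc <- c(0, 0.1, 0.3, 1, 3, 10, 30, 60, 100)
#' resp <- 100 / (1 + (conc / 2.08)^1)
#' fit_ic50(data.frame(inhibitor_uM = conc, pct_control = resp))$ic50_um
fit_ic50 <- function(data, floating = FALSE) {
  stopifnot(is.data.frame(data),
            all(c("inhibitor_uM", "pct_control") %in% names(data)))
  d <- as_tibble(data)
  if (any(d$inhibitor_uM < 0)) abort("inhibitor concentrations must be >= 0")
  if (length(unique(d$inhibitor_uM)) < 5) {
    abort("need at least 5 concentration levels to fit an IC50")
  }
  if (all(d$pct_control == 0)) abort("all-zero response; nothing to fit")
  pos <- d[d$inhibitor_uM > 0, ]
  trend <- stats::cor(log(pos$inhibitor_uM), pos$pct_control,
                      method = "spearman")
  if (is.finite(trend) && trend > 0) {
    abort("response increases with inhibitor concentration; not an inhibition curve")
  }
  start_ic50 <- exp(mean(log(range(pos$inhibitor_uM))))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- if (floating) {
    minpack.lm::nlsLM(
      pct_control ~ bottom + (top - bottom) / (1 + (inhibitor_uM / ic50)^h),
      data = d,
      start = list(ic50 = start_ic50, h = 1, top = max(d$pct_control),
                   bottom = min(d$pct_control)),
      lower = c(1e-6, 0.1, 0, -20), control = ctrl)
  } else {
    minpack.lm::nlsLM(
      pct_control ~ 100 / (1 + (inhibitor_uM / ic50)^h),
      data = d, start = list(ic50 = start_ic50, h = 1),
      lower = c(1e-6, 0.1), control = ctrl)
  }
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((d$pct_control - mean(d$pct_control))^2)
  structure(list(
    ic50_um = unname(cf["ic50"]),
    hill_slope = unname(cf["h"]),
    top = if (floating) unname(cf["top"]) else 100,
    bottom = if (floating) unname(cf["bottom"]) else 0,
    floating = floating,
    r_squared = r2,
    n = nrow(d),
    fit = fit
  ), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit> IC50 = %.3g uM, Hill slope = %.3g, R2 = %.4f (%s asymptotes)\n",
              x$ic50_um, x$hill_slope, x$r_squared,
              if (x$floating) "floating" else "fixed"))
  invisible(x)
}

#' @export
tidy.ic50_fit <- function(x, ...) {
  tibble(term = c("ic50_um", "hill_slope", "top", "bottom"),
         estimate = c(x$ic50_um, x$hill_slope, x$top, x$bottom))
}

#' @export
glance.ic50_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n, floating = x$floating)
}

#' Scale an IC50 to an inhibition constant
#'
#' Interspecies ratio scaling: the target-species Ki is estimated from the
#' target IC50 and the reference species' experimental IC50/Ki pair,
#' `Ki_target = IC50_target * Ki_ref / IC50_ref`. For the classical
#' substrate-competition correction use [cheng_prusoff()].
#'
#' @param ic50_target_um IC50 in the target system, uM.
#' @param ic50_reference_um IC50 in the reference system, uM.
#' @param ki_reference_um literature Ki in the reference system, uM.
#' @return estimated Ki, uM.
#' @export
ki_from_ic50 <- function(ic50_target_um, ic50_reference_um, ki_reference_um) {
  check_positive(ic50_target_um, "ic50_target_um")
  check_positive(ic50_reference_um, "ic50_reference_um")
  check_positive(ki_reference_um, "ki_reference_um")
  ic50_target_um * ki_reference_um / ic50_reference_um
}

#' Cheng-Prusoff conversion of an IC50 to Ki
#'
#' `Ki = IC50 / (1 + S / Km)` for a competitive inhibitor assayed at
#' substrate concentration `S` with Michaelis constant `Km`.
#'
#' @param ic50_um IC50, uM.
#' @param substrate_um substrate concentration in the assay, uM.
#' @param km_um substrate Michaelis constant, uM.
#' @return Ki, uM.
#' @export
cheng_prusoff <- function(ic50_um, substrate_um, km_um) {
  check_positive(ic50_um, "ic50_um")
  check_nonnegative(substrate_um, "substrate_um")
  check_positive(km_um, "km_um")
  ic50_um / (1 + substrate_um / km_um)
}
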