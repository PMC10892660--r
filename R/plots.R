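# ggplot2 layers for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   scale_y_log10 geom_abline theme_minimal geom_ribbon geom_col
NULL

#' Plot a simulated plasma concentration-time profile
#'
#' @param object a `pbpk_sim`.
#' @param log_y log-scale concentration axis (default TRUE).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pbpk_sim <- function(object, log_y = TRUE, ...) {
  d <- object$profile[object$profile$conc_ng_per_ml > 0 | !log_y, ]
  p <- ggplot(d, aes(x = .data$time_h, y = .data$conc_ng_per_ml)) +
    geom_line(linewidth = 0.7) +
    labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
         title = sprintf("%s, %s", object$metadata$compound,
                         object$metadata$species)) +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Plot victim profiles with and without the perpetrator
#'
#' @param object a `ddi_result`.
#' @param log_y log-scale concentration axis (default TRUE).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ddi_result <- function(object, log_y = TRUE, ...) {
  d <- bind_rows(
    mutate(object$alone_profile, arm = "victim alone"),
    mutate(object$combo_profile, arm = "victim + perpetrator"))
  if (log_y) d <- d[d$conc_ng_per_ml > 0, ]
  p <- ggplot(d, aes(x = .data$time_h, y = .data$conc_ng_per_ml,
                     colour = .data$arm)) +
    geom_line(linewidth = 0.7) +
    labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
         colour = NULL,
         title = sprintf("%s with/without %s (%s)",
                         object$scenario$victim$name,
                         object$scenario$perpetrator$name,
                         object$scenario$species)) +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Plot a fitted inhibition curve
#'
#' @param object an `ic50_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- as_tibble(stats::model.frame(object$fit))
  pos <- d$inhibitor_uM[d$inhibitor_uM > 0]
  grid <- tibble(inhibitor_uM = exp(seq(log(min(pos) / 3),
                                        log(max(pos) * 3), length.out = 200)))
  grid$pct_control <- object$bottom + (object$top - object$bottom) /
    (1 + (grid$inhibitor_uM / object$ic50_um)^object$hill_slope)
  ggplot(d[d$inhibitor_uM > 0, ],
         aes(x = .data$inhibitor_uM, y = .data$pct_control)) +
    geom_point() +
    geom_line(data = grid) +
    ggplot2::scale_x_log10() +
    labs(x = "Inhibitor (uM)", y = "Activity (% of control)",
         title = sprintf("IC50 = %.3g uM (R2 = %.3f)",
                         object$ic50_um, object$r_squared)) +
    theme_minimal()
}

#' Goodness-of-fit plot of predicted vs observed values
#'
#' Identity line plus the 1.25-fold (dotted) and 2-fold (dashed) bands
#' conventionally used to judge PBPK predictions.
#'
#' @param predicted,observed positive numeric vectors.
#' @param label optional point labels.
#' @return a ggplot.
#' @export
plot_gof <- function(predicted, observed, label = NULL) {
  fc <- fold_classification(predicted, observed)
  d <- fc$pairs
  if (!is.null(label)) d$label <- label
  ggplot(d, aes(x = .data$observed, y = .data$predicted,
                colour = .data$band)) +
    geom_abline(slope = 1, intercept = 0) +
    geom_abline(slope = 1, intercept = log10(1.25), linetype = "dotted") +
    geom_abline(slope = 1, intercept = -log10(1.25), linetype = "dotted") +
    geom_abline(slope = 1, intercept = log10(2), linetype = "dashed") +
    geom_abline(slope = 1, intercept = -log10(2), linetype = "dashed") +
    geom_point(size = 2) +
    ggplot2::scale_x_log10() + scale_y_log10() +
    labs(x = "Observed", y = "Predicted", colour = NULL) +
    theme_minimal()
}

#' Tornado-style plot of a sensitivity scan
#'
#' @param scan result of [sensitivity_scan()].
#' @return a ggplot.
#' @export
plot_sensitivity <- function(scan) {
  d <- tidyr::pivot_longer(scan, c("sc_cmax", "sc_aucinf"),
                           names_to = "output", values_to = "sc") |>
    mutate(output = dplyr::recode(.data$output, sc_cmax = "Cmax",
                                  sc_aucinf = "AUCinf"))
  ggplot(d, aes(x = .data$sc,
                y = stats::reorder(.data$parameter, abs(.data$sc)),
                fill = .data$output)) +
    geom_col(position = "dodge") +
    ggplot2::geom_vline(xintercept = c(-0.1, 0.1), linetype = "dotted") +
    labs(x = "Sensitivity coefficient", y = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot a Monte-Carlo prediction interval
#'
#' @param interval result of [prediction_interval()].
#' @param log_y log-scale concentration axis (default TRUE).
#' @return a ggplot.
#' @export
plot_prediction_interval <- function(interval, log_y = TRUE) {
  d <- interval
  if (log_y) d <- d[d$point > 0 & d$lo > 0, ]
  p <- ggplot(d, aes(x = .data$time_h)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), alpha = 0.25) +
    geom_line(aes(y = .data$point)) +
    labs(x = "Time (h)", y = "Plasma concentration (ng/mL)") +
    theme_minimal()
  if (log_y) p <- p + scale_y_log10()
  p
}
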