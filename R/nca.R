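# Noncompartmental analysis of concentration-time profiles.

# trapezoid AUC over one interval; linear when rising or flat (or when a
# bound is zero), log-trapezoid when declining between positive values
interval_auc <- function(t1, t2, c1, c2, method = "linuplogdown") {
  dt <- t2 - t1
  if (method == "linear" || c2 >= c1 || c1 <= 0 || c2 <= 0) {
    dt * (c1 + c2) / 2
  } else {
    dt * (c1 - c2) / log(c1 / c2)
  }
}

auc_trapezoid <- function(time, conc, method = "linuplogdown") {
  n <- length(time)
  if (n < 2) return(0)
  sum(vapply(seq_len(n - 1), function(i) {
    interval_auc(time[i], time[i + 1], conc[i], conc[i + 1], method)
  }, numeric(1)))
}

# choose the terminal log-linear window (>= min_points points, excluding
# Tmax) maximizing adjusted R^2
select_lambda_z <- function(time, conc, min_points = 3) {
  pos <- conc > 0
  t <- time[pos]; c <- conc[pos]
  if (length(t) < min_points) return(NULL)
  tmax_idx <- which.max(c)
  last <- length(t)
  best <- NULL
  for (start in seq(tmax_idx + 1, last - min_points + 1)) {
    if (start < 1) next
    idx <- start:last
    if (length(idx) < min_points) next
    fit <- stats::lm(log(c[idx]) ~ t[idx])
    slope <- stats::coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    # noiseless profiles legitimately produce perfect fits
    adj <- suppressWarnings(summary(fit)$adj.r.squared)
    if (is.null(best) || adj > best$adj_r2 + 1e-12) {
      best <- list(lambda_z = -slope, adj_r2 = adj, n = length(idx),
                   t_first = t[idx[1]])
    }
  }
  best
}

#' Noncompartmental analysis of a single concentration-time profile
#'
#' Computes Cmax and Tmax by direct maximum, AUC to the last positive
#' concentration by the linear-up/log-down trapezoid (pure linear
#' selectable), the terminal slope `lambda_z` by log-linear regression
#' over the terminal window that maximizes adjusted R-squared (minimum 3
#' points, Tmax excluded; a manual window is available), the terminal
#' half-life `ln 2 / lambda_z`, the extrapolated
#' `AUCinf = AUClast + Clast / lambda_z`, and — when a dose is supplied —
#' the apparent oral clearance `CL/F = dose / AUCinf`.
#'
#' When no terminal decline can be identified, `lambda_z` and everything
#' depending on it are returned as `NA` with `lambda_z_flag` set.
#'
#' @param data data frame with columns `time_h` (strictly increasing) and
#'   `conc_ng_per_ml` (>= 0).
#' @param dose dose amount; with `dose_per_kg = TRUE` (default) in mg/kg
#'   giving CL/F in L/h/kg, otherwise in mg giving CL/F in L/h.
#' @param dose_per_kg whether `dose` is per kg body weight.
#' @param auc_method `"linuplogdown"` (default) or `"linear"`.
#' @param lambda_z_window optional numeric vector `c(t_start, t_end)` in h
#'   restricting the terminal fit to samples inside the window.
#' @param min_points minimum number of terminal points (default 3).
#' @return a one-row tibble: `cmax`, `tmax_h`, `auc_last`, `auc_inf`,
#'   `t_half_h`, `lambda_z_per_h`, `n_lambda_points`, `adj_r2`,
#'   `extrapolated_fraction`, `cl_f`, `lambda_z_flag`.
#' @export
#' @examples
#' tt <- seq(0, 72, by = 0.5)
#' prof <- data.frame(time_h = tt, conc_ng_per_ml = 100 * exp(-0.1 * tt))
#' nca_single(prof)
nca_single <- function(data, dose = NULL, dose_per_kg = TRUE,
                       auc_method = c("linuplogdown", "linear"),
                       lambda_z_window = NULL, min_points = 3) {
  auc_method <- match.arg(auc_method)
  stopifnot(is.data.frame(data),
            all(c("time_h", "conc_ng_per_ml") %in% names(data)))
  t <- data$time_h
  conc <- data$conc_ng_per_ml
  if (is.unsorted(t, strictly = TRUE)) abort("time_h must be strictly increasing")
  if (any(conc < 0)) abort("concentrations must be nonnegative")
  if (sum(conc > 0) < 4) abort("need at least 4 positive concentrations")

  cmax <- max(conc)
  tmax <- t[which.max(conc)]
  keep <- seq_len(max(which(conc > 0)))
  auc_last <- auc_trapezoid(t[keep], conc[keep], auc_method)
  c_last <- conc[max(which(conc > 0))]

  lt <- t; lc <- conc
  if (!is.null(lambda_z_window)) {
    sel <- t >= lambda_z_window[1] & t <= lambda_z_window[2] & conc > 0
    lz <- if (sum(sel) >= min_points) {
      fit <- stats::lm(log(conc[sel]) ~ t[sel])
      slope <- stats::coef(fit)[[2]]
      if (is.finite(slope) && slope < 0) {
        list(lambda_z = -slope,
             adj_r2 = suppressWarnings(summary(fit)$adj.r.squared),
             n = sum(sel))
      } else NULL
    } else NULL
  } else {
    lz <- select_lambda_z(lt, lc, min_points)
  }

  if (is.null(lz)) {
    lam <- NA_real_; t_half <- NA_real_; auc_inf <- NA_real_
    n_lam <- NA_integer_; adj <- NA_real_; extrap <- NA_real_
    flag <- "no terminal decline"
  } else {
    lam <- lz$lambda_z
    t_half <- log(2) / lam
    auc_inf <- auc_last + c_last / lam
    n_lam <- lz$n
    adj <- lz$adj_r2
    extrap <- (auc_inf - auc_last) / auc_inf
    flag <- NA_character_
  }
  cl_f <- if (!is.null(dose) && is.finite(auc_inf)) {
    dose * 1000 / auc_inf # mg[/kg] over ng.h/mL -> L/h[/kg]
  } else {
    NA_real_
  }
  tibble(cmax = cmax, tmax_h = tmax, auc_last = auc_last, auc_inf = auc_inf,
         t_half_h = t_half, lambda_z_per_h = lam,
         n_lambda_points = n_lam, adj_r2 = adj,
         extrapolated_fraction = extrap, cl_f = cl_f, lambda_z_flag = flag)
}

#' Group-level noncompartmental analysis
#'
#' Runs [nca_single()] per subject, summarises each PK parameter as
#' arithmetic mean and SD per group, and, for exactly two groups, adds an
#' unpaired two-sided Student's t-test per parameter.
#'
#' @param data data frame with columns `subject`, `group`, `time_h`,
#'   `conc_ng_per_ml` and optionally `dose` (constant within subject).
#' @param ... passed to [nca_single()].
#' @return a list with `subjects` (per-subject parameter tibble),
#'   `summary` (group mean/sd per parameter) and `comparison` (per
#'   parameter: group means, mean ratio, t-test p-value; only for two
#'   groups).
#' @export
nca_group <- function(data, ...) {
  stopifnot(all(c("subject", "group", "time_h", "conc_ng_per_ml")
                %in% names(data)))
  d <- as_tibble(data)
  counts <- dplyr::count(dplyr::distinct(d, .data$subject, .data$group),
                         .data$group)
  if (any(counts$n < 2)) abort("need at least 2 subjects per group")

  subjects <- d |>
    group_by(.data$subject, .data$group) |>
    dplyr::group_modify(function(g, key) {
      dose <- if ("dose" %in% names(g)) g$dose[1] else NULL
      nca_single(g[order(g$time_h), c("time_h", "conc_ng_per_ml")],
                 dose = dose, ...)
    }) |>
    ungroup()

  params <- c("cmax", "tmax_h", "auc_last", "auc_inf", "t_half_h", "cl_f")
  long <- tidyr::pivot_longer(subjects, dplyr::any_of(params),
                              names_to = "parameter", values_to = "value")
  summ <- long |>
    group_by(.data$group, .data$parameter) |>
    summarise(n = sum(is.finite(.data$value)),
              mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value, na.rm = TRUE),
              .groups = "drop")

  comparison <- NULL
  groups <- sort(unique(d$group))
  if (length(groups) == 2) {
    comparison <- long |>
      group_by(.data$parameter) |>
      dplyr::group_modify(function(g, key) {
        a <- g$value[g$group == groups[1] & is.finite(g$value)]
        b <- g$value[g$group == groups[2] & is.finite(g$value)]
        if (length(a) < 2 || length(b) < 2) {
          return(tibble(mean_1 = mean(a), mean_2 = mean(b),
                        ratio = mean(b) / mean(a), p_value = NA_real_,
                        degenerate = TRUE))
        }
        degen <- stats::sd(c(a - mean(a), b - mean(b))) == 0
        p <- if (degen) 1 else stats::t.test(a, b)$p.value
        tibble(mean_1 = mean(a), mean_2 = mean(b), ratio = mean(b) / mean(a),
               p_value = p, degenerate = degen)
      }) |>
      ungroup() |>
      mutate(group_1 = groups[1], group_2 = groups[2])
  }
  list(subjects = subjects, summary = summ, comparison = comparison)
}

#' Read a concentration-time profile CSV
#'
#' Expected columns: `time_h`, `conc_ng_per_ml`, optionally `subject`,
#' `group`, `dose`.
#' @param path CSV path.
#' @return tibble.
#' @export
read_profile_csv <- function(path) {
  d <- read_csv_strict(path)
  if (!all(c("time_h", "conc_ng_per_ml") %in% names(d))) {
    abort("profile CSV needs columns time_h, conc_ng_per_ml")
  }
  d
}
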