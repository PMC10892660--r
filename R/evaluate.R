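# Model performance metrics: MRD, GMFE, DDI ratios, fold classification,
# Monte-Carlo prediction intervals.

#' Mean relative deviation between observed and predicted profiles
#'
#' Multiplicative goodness of fit for concentration-time data:
#' `MRD = 10^x` with `x` the root-mean-square of the log10 residuals over
#' the common timepoints. Identical profiles give 1; an MRD of 2 means
#' predictions deviate 2-fold on average.
#'
#' @param observed,predicted data frames with columns `time_h` and
#'   `conc_ng_per_ml`; they are aligned on exactly matching timepoints.
#' @return MRD (dimensionless, >= 1).
#' @export
#' @examples
#' obs <- data.frame(time_h = 1:3, conc_ng_per_ml = c(10, 5, 2))
#' mrd(obs, obs) # 1
mrd <- function(observed, predicted) {
  stopifnot(is.data.frame(observed), is.data.frame(predicted))
  m <- dplyr::inner_join(
    dplyr::select(as_tibble(observed), "time_h", obs = "conc_ng_per_ml"),
    dplyr::select(as_tibble(predicted), "time_h", pred = "conc_ng_per_ml"),
    by = "time_h")
  if (nrow(m) == 0) abort("no common timepoints between profiles")
  if (any(m$obs <= 0) || any(m$pred <= 0)) {
    abort("MRD requires strictly positive concentrations")
  }
  10^sqrt(mean((log10(m$obs) - log10(m$pred))^2))
}

#' Geometric mean fold error of predicted/observed ratios
#'
#' `GMFE = 10^(mean(|log10(ratio)|))` over a set of predicted/observed PK
#' parameter ratios. Symmetric under ratio inversion; 1 for perfect
#' prediction, 2 for an average 2-fold error.
#'
#' @param ratios numeric vector of predicted/observed ratios (> 0).
#' @return GMFE (dimensionless, >= 1).
#' @export
#' @examples
#' gmfe(c(2.05, 1.46)) # ~1.73
gmfe <- function(ratios) {
  if (length(ratios) == 0) abort("`ratios` must be nonempty")
  check_positive(ratios, "ratios")
  10^mean(abs(log10(ratios)))
}

#' DDI exposure ratios (co-administration over single administration)
#'
#' @param alone,combo one-row PK parameter tibbles (as from
#'   [nca_single()]) for the victim alone and co-administered with the
#'   perpetrator; both must carry `auc_inf` and `cmax`.
#' @return tibble with `ddi_auc_ratio` and `ddi_cmax_ratio`.
#' @export
#' @examples
#' ddi_ratios(data.frame(cmax = 98.5, auc_inf = 157),
#'            data.frame(cmax = 281, auc_inf = 408))
ddi_ratios <- function(alone, combo) {
  for (nm in c("cmax", "auc_inf")) {
    if (!nm %in% names(alone) || !nm %in% names(combo)) {
      abort(sprintf("both parameter sets must carry `%s`", nm))
    }
    if (!is.finite(alone[[nm]][1]) || !is.finite(combo[[nm]][1])) {
      abort(sprintf("`%s` is missing in one of the parameter sets", nm))
    }
  }
  tibble(ddi_auc_ratio = combo$auc_inf[1] / alone$auc_inf[1],
         ddi_cmax_ratio = combo$cmax[1] / alone$cmax[1])
}

#' Classify prediction errors into fold bands
#'
#' Each predicted/observed pair is classified by its ratio, symmetric in
#' log space, into "within 1.25-fold", "within 2-fold" or
#' "outside 2-fold". The 2-fold band is the conventional PBPK success
#' criterion.
#'
#' @param predicted,observed numeric vectors (> 0) of equal length.
#' @return a list with `pairs` (tibble: predicted, observed, ratio, band)
#'   and `counts` (tibble of band counts), plus `pass_2fold` (all pairs
#'   within 2-fold).
#' @export
#' @examples
#' fold_classification(144, 98.5)$pairs$band
fold_classification <- function(predicted, observed) {
  check_positive(predicted, "predicted")
  check_positive(observed, "observed")
  stopifnot(length(predicted) == length(observed))
  ratio <- predicted / observed
  dev <- pmax(ratio, 1 / ratio)
  band <- dplyr::case_when(
    dev <= 1.25 ~ "within 1.25-fold",
    dev <= 2 ~ "within 2-fold",
    TRUE ~ "outside 2-fold")
  band <- factor(band, levels = c("within 1.25-fold", "within 2-fold",
                                  "outside 2-fold"))
  pairs <- tibble(predicted = predicted, observed = observed,
                  ratio = ratio, band = band)
  counts <- dplyr::count(pairs, .data$band, .drop = FALSE)
  list(pairs = pairs, counts = counts,
       pass_2fold = all(dev <= 2))
}

#' Evaluation report for a predicted profile and PK parameter set
#'
#' Convenience wrapper assembling the quantitative model-evaluation
#' metrics: MRD of the concentration profile, GMFE of the PK parameter
#' ratios, the fold classification, and the pass flags (MRD <= 2 and
#' GMFE <= 2).
#'
#' @param observed_profile,predicted_profile profiles for [mrd()] (or
#'   `NULL` to skip).
#' @param predicted_params,observed_params named numeric vectors of PK
#'   parameters to compare (matched by name).
#' @return a list of class `pbpk_evaluation`.
#' @export
evaluation_report <- function(observed_profile = NULL,
                              predicted_profile = NULL,
                              predicted_params = NULL,
                              observed_params = NULL) {
  out <- list(mrd = NULL, gmfe = NULL, ratios = NULL, folds = NULL,
              pass_mrd = NA, pass_gmfe = NA)
  if (!is.null(observed_profile) && !is.null(predicted_profile)) {
    out$mrd <- mrd(observed_profile, predicted_profile)
    out$pass_mrd <- out$mrd <= 2
  }
  if (!is.null(predicted_params)) {
    common <- intersect(names(predicted_params), names(observed_params))
    if (length(common) == 0) abort("no common PK parameters to compare")
    r <- predicted_params[common] / observed_params[common]
    out$ratios <- tibble(parameter = common,
                         predicted = as.numeric(predicted_params[common]),
                         observed = as.numeric(observed_params[common]),
                         ratio = as.numeric(r))
    out$gmfe <- gmfe(r)
    out$pass_gmfe <- out$gmfe <= 2
    out$folds <- fold_classification(as.numeric(predicted_params[common]),
                                     as.numeric(observed_params[common]))
  }
  structure(out, class = "pbpk_evaluation")
}

#' @export
print.pbpk_evaluation <- function(x, ...) {
  cat("<pbpk_evaluation>\n")
  if (!is.null(x$mrd)) cat(sprintf("  MRD  %.3f (pass <= 2: %s)\n",
                                   x$mrd, x$pass_mrd))
  if (!is.null(x$gmfe)) cat(sprintf("  GMFE %.3f (pass <= 2: %s)\n",
                                    x$gmfe, x$pass_gmfe))
  if (!is.null(x$folds)) print(x$folds$counts)
  invisible(x)
}

#' Monte-Carlo prediction interval for a simulated plasma profile
#'
#' Repeats a scenario simulation over a virtual population whose
#' parameters are drawn lognormally around the point estimates (unit
#' median; the coefficient of variation is supplied per parameter), and
#' summarises the plasma profile as per-timepoint empirical percentiles.
#' Deterministic given the seed.
#'
#' @param scenario a [pbpk_scenario()] (single compound) or
#'   [ddi_scenario()]; for a DDI scenario the victim profile under
#'   co-administration is summarised.
#' @param pop population spec: list with `n_subjects` (>= 2), `cv` (named
#'   vector of lognormal CVs; names are sensitivity-style parameter paths,
#'   see [sensitivity_scan()]), `seed`, and optional `level`
#'   (default 0.95).
#' @return a tibble `time_h`, `point`, `mean`, `lo`, `hi` with the
#'   population spec in attribute `population`.
#' @export
prediction_interval <- function(scenario, pop) {
  stopifnot(is.list(pop), !is.null(pop$seed))
  n <- pop$n_subjects
  if (is.null(n) || n < 2) abort("population needs n_subjects >= 2")
  cv <- pop$cv %||% numeric()
  check_nonnegative(cv, "cv")
  level <- pop$level %||% 0.95
  alpha <- (1 - level) / 2

  base <- scenario_profile(scenario)
  draws <- withr_seed(pop$seed, {
    purrr::map(seq_len(n), function(i) {
      sc <- scenario
      for (p in names(cv)) {
        if (cv[[p]] > 0) {
          sdlog <- sqrt(log(1 + cv[[p]]^2))
          fac <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          sc <- perturb_scenario(sc, p, factor = fac)
        }
      }
      scenario_profile(sc)$conc_ng_per_ml
    })
  })
  mat <- do.call(cbind, draws)
  out <- tibble(
    time_h = base$time_h,
    point = base$conc_ng_per_ml,
    mean = rowMeans(mat),
    lo = apply(mat, 1, stats::quantile, probs = alpha, names = FALSE),
    hi = apply(mat, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  )
  attr(out, "population") <- pop
  out
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
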