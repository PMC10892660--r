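#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange left_join bind_rows group_by
#'   summarise ungroup pull rename across
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# unit conversions used throughout: internal engine units are
# time h, volume mL, amount nmol, concentration nmol/mL (== umol/L == uM)

mg_to_nmol <- function(mg, mw) mg * 1e6 / mw
nmol_to_ng <- function(nmol, mw) nmol * mw
uM_to_ng_ml <- function(um, mw) um * mw

extdata <- function(...) {
  path <- system.file("extdata", ..., package = "pbpkddi", mustWork = TRUE)
  path
}

read_csv_strict <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive and finite", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be nonnegative and finite", name))
  }
  invisible(x)
}

#' Reported study tables bundled with the package
#'
#' Returns one of the transcribed summary tables that parameterize and
#' benchmark the saxagliptin/nicardipine interaction workflow: observed and
#' predicted PK parameters, predicted/observed fold errors, DDI summaries,
#' and the inputs of the static `1 + [I]/Ki` interaction index.
#'
#' @param name one of `"rat_victim_ddi_observed"`, `"gof_saxagliptin"`,
#'   `"gof_nicardipine"`, `"fold_error_studies"`, `"gmfe_printed"`,
#'   `"ddi_summary"`, `"static_model_inputs"`, `"invitro_inputs"`.
#' @return a tibble.
#' @export
#' @examples
#' reported_table("ddi_summary")
reported_table <- function(name = c("rat_victim_ddi_observed",
                                    "gof_saxagliptin", "gof_nicardipine",
                                    "fold_error_studies", "gmfe_printed",
                                    "ddi_summary", "static_model_inputs",
                                    "invitro_inputs")) {
  name <- match.arg(name)
  read_csv_strict(extdata("reported", paste0(name, ".csv")))
}
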