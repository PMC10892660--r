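#' Define a drug for PBPK simulation
#'
#' A compound bundles the physicochemical and ADME parameters the engine
#' needs: molecular weight, lipophilicity (logD at pH 7.4), a single pKa
#' with its compound type, reference solubility, species-specific plasma
#' fraction unbound, specific intestinal permeability, cellular
#' (transmembrane) permeability with an explicit unit, formulations
#' (solution or Weibull-dissolving tablet), clearance processes
#' (CYP-mediated intrinsic clearance, renal plasma clearance, or a total
#' hepatic elimination half-life) and competitive-inhibition constants
#' against CYP enzymes.
#'
#' @param name compound name.
#' @param molecular_weight_g_mol molecular weight, g/mol.
#' @param lipophilicity_logd74 logD at pH 7.4 (dimensionless).
#' @param pka acid dissociation constant (single value).
#' @param compound_type `"acid"`, `"base"` or `"neutral"`.
#' @param solubility_mg_per_ml aqueous solubility at the reference pH.
#' @param fraction_unbound named list/vector of plasma fraction unbound per
#'   species, each in (0, 1].
#' @param intestinal_permeability_1e6_cm_s specific intestinal
#'   permeability in 1e-6 cm/s.
#' @param cellular_permeability list with `value` and `unit`
#'   (`"cm/s"` or `"1e-6 cm/s"`).
#' @param clearance list of clearance processes; each a list with `kind`
#'   (`"enzyme_mediated"`, `"renal"`, `"total_hepatic_halflife"`),
#'   `species`, and the kind's parameter (`clint_ul_min_pmol` + `enzyme`,
#'   `renal_clearance_ml_min_kg`, or `hepatic_t_half_min`).
#' @param formulations list of formulation specs; each a list with `name`,
#'   `kind` (`"solution"`/`"tablet"`) and, for tablets,
#'   `dissolution_shape` and `dissolution_time_min` (time to 50%%
#'   dissolved).
#' @param inhibitions list of competitive inhibition specs; each a list
#'   with `species`, `enzyme`, `ki_um`, `mechanism = "competitive"`.
#' @param solubility_ref_ph reference pH of the solubility value.
#' @return an object of class `pbpk_compound`.
#' @seealso [read_compound()] to load the bundled YAML definitions.
#' @export
compound <- function(name, molecular_weight_g_mol, lipophilicity_logd74,
                     pka, compound_type, solubility_mg_per_ml,
                     fraction_unbound, intestinal_permeability_1e6_cm_s,
                     cellular_permeability, clearance = list(),
                     formulations = list(list(name = "solution",
                                              kind = "solution")),
                     inhibitions = list(), solubility_ref_ph = 7) {
  check_positive(molecular_weight_g_mol, "molecular_weight_g_mol")
  check_positive(solubility_mg_per_ml, "solubility_mg_per_ml")
  check_positive(intestinal_permeability_1e6_cm_s,
                 "intestinal_permeability_1e6_cm_s")
  if (!compound_type %in% c("acid", "base", "neutral")) {
    abort("compound_type must be acid, base or neutral")
  }
  fu <- unlist(fraction_unbound)
  if (any(fu <= 0 | fu > 1)) {
    abort("fraction_unbound must lie in (0, 1] for every species")
  }
  if (!is.list(cellular_permeability) ||
      !all(c("value", "unit") %in% names(cellular_permeability))) {
    abort("cellular_permeability must carry `value` and `unit`")
  }
  if (!cellular_permeability$unit %in% c("cm/s", "1e-6 cm/s")) {
    abort("cellular_permeability unit must be \"cm/s\" or \"1e-6 cm/s\"")
  }
  check_positive(cellular_permeability$value, "cellular_permeability")

  for (cl in clearance) {
    if (!cl$kind %in% c("enzyme_mediated", "renal", "total_hepatic_halflife"))
      abort(sprintf("unknown clearance kind `%s`", cl$kind))
    par <- switch(cl$kind,
      enzyme_mediated = cl$clint_ul_min_pmol,
      renal = cl$renal_clearance_ml_min_kg,
      total_hepatic_halflife = cl$hepatic_t_half_min)
    if (is.null(par)) abort("clearance process missing its rate parameter")
    check_positive(par, paste0("clearance.", cl$kind))
    if (cl$kind == "enzyme_mediated" && is.null(cl$enzyme))
      abort("enzyme_mediated clearance needs an `enzyme`")
  }
  for (f in formulations) {
    if (!f$kind %in% c("solution", "tablet"))
      abort(sprintf("unknown formulation kind `%s`", f$kind))
    if (f$kind == "tablet") {
      check_positive(f$dissolution_shape, "dissolution_shape")
      check_positive(f$dissolution_time_min, "dissolution_time_min")
    }
  }
  for (inh in inhibitions) {
    check_positive(inh$ki_um, "ki_um")
    if (!identical(inh$mechanism, "competitive"))
      abort("only competitive inhibition is supported")
  }

  structure(list(
    name = name,
    molecular_weight = molecular_weight_g_mol,
    logd74 = lipophilicity_logd74,
    pka = pka,
    compound_type = compound_type,
    solubility_mg_per_ml = solubility_mg_per_ml,
    solubility_ref_ph = solubility_ref_ph,
    fraction_unbound = as.list(fu),
    peff_1e6_cm_s = intestinal_permeability_1e6_cm_s,
    cellular_permeability = cellular_permeability,
    clearance = clearance,
    formulations = formulations,
    inhibitions = inhibitions
  ), class = "pbpk_compound")
}

#' @export
print.pbpk_compound <- function(x, ...) {
  cat(sprintf("<pbpk_compound> %s (MW %.5g, logD7.4 %.3g, pKa %.3g %s)\n",
              x$name, x$molecular_weight, x$logd74, x$pka, x$compound_type))
  cat(sprintf("  %d clearance process(es), %d formulation(s), %d inhibition(s)\n",
              length(x$clearance), length(x$formulations),
              length(x$inhibitions)))
  invisible(x)
}

#' Load a compound definition from YAML
#'
#' Reads the YAML compound format shipped under
#' `extdata/compounds/` (`saxagliptin.yaml`, `nicardipine.yaml`), which
#' mirrors the model input tables field for field with units embedded in
#' the keys.
#'
#' @param path path to a YAML file, or one of the bundled names
#'   `"saxagliptin"`/`"nicardipine"`.
#' @param cellular_permeability_unit_hint optional override for the unit of
#'   the cellular permeability entry (`"cm/s"` or `"1e-6 cm/s"`), for
#'   files whose printed unit is ambiguous.
#' @return a `pbpk_compound`.
#' @export
#' @examples
#' sxg <- read_compound("saxagliptin")
#' sxg$molecular_weight
read_compound <- function(path, cellular_permeability_unit_hint = NULL) {
  if (!file.exists(path) && path %in% c("saxagliptin", "nicardipine")) {
    path <- extdata("compounds", paste0(path, ".yaml"))
  }
  raw <- yaml::read_yaml(path)
  cp <- raw$cellular_permeability
  if (!is.null(cellular_permeability_unit_hint)) {
    cp$unit <- cellular_permeability_unit_hint
  }
  compound(
    name = raw$name,
    molecular_weight_g_mol = raw$molecular_weight_g_mol,
    lipophilicity_logd74 = raw$lipophilicity_logd74,
    pka = raw$pka,
    compound_type = raw$compound_type,
    solubility_mg_per_ml = raw$solubility_mg_per_ml,
    solubility_ref_ph = raw$solubility_ref_ph %||% 7,
    fraction_unbound = raw$fraction_unbound,
    intestinal_permeability_1e6_cm_s =
      raw[["specific_intestinal_permeability_1e-6_cm_s"]],
    cellular_permeability = cp,
    clearance = raw$clearance %||% list(),
    formulations = raw$formulations %||%
      list(list(name = "solution", kind = "solution")),
    inhibitions = raw$inhibitions %||% list()
  )
}

# species accessors ---------------------------------------------------------

fu_plasma <- function(cmp, species) {
  fu <- cmp$fraction_unbound[[species]]
  if (is.null(fu)) abort(sprintf("no fraction_unbound for species `%s`",
                                 species))
  fu
}

clearances_for <- function(cmp, species) {
  Filter(function(cl) is.null(cl$species) || cl$species == species,
         cmp$clearance)
}

inhibitions_for <- function(cmp, species) {
  Filter(function(x) is.null(x$species) || x$species == species,
         cmp$inhibitions)
}

formulation_spec <- function(cmp, formulation) {
  for (f in cmp$formulations) if (identical(f$name, formulation)) return(f)
  abort(sprintf("compound %s has no formulation `%s`", cmp$name, formulation))
}

cellular_permeability_cm_h <- function(cmp) {
  v <- cmp$cellular_permeability$value
  if (cmp$cellular_permeability$unit == "1e-6 cm/s") v <- v * 1e-6
  v * 3600
}

# partitioning --------------------------------------------------------------

# effective plasma composition for the tissue-composition partitioning
# scheme; the protein fraction is chosen so that the plasma affinity is
# exactly one at P = 1 (water + lipid + 0.37 * protein == 1)
KP_PROTEIN_SORPTION <- 0.37
KP_PLASMA <- c(water = 0.96, lipid = 0.0035,
               protein = (1 - 0.96 - 0.0035) / KP_PROTEIN_SORPTION)
KP_RBC_COMPOSITION <- c(f_water = 0.66, f_lipid = 0.005, f_protein = 0.33)

tissue_affinity <- function(p, f_water, f_lipid, f_protein) {
  f_water + p * f_lipid + KP_PROTEIN_SORPTION * f_protein
}

#' Tissue-to-plasma partition coefficients from tissue composition
#'
#' Computes one equilibrium partition coefficient (Kp, total tissue over
#' total plasma concentration) per organ from the organ's water, lipid and
#' protein content: drug affinity for a phase mixture is modeled as
#' `water + 10^logD7.4 * lipid + 0.37 * protein`, and Kp is the ratio of
#' the tissue affinity to that of an effective plasma composition (96%
#' water, 0.35% lipid, protein remainder). Ionization is carried by using
#' the distribution coefficient at pH 7.4 rather than logP; all body
#' compartments are treated at pH 7.4. The scheme name is recorded in the
#' result's metadata and individual Kp values can be overridden (e.g. to
#' inject values exported from another platform).
#'
#' @param cmp a [compound()].
#' @param phys a [load_physiology()] object.
#' @param overrides optional named numeric vector of per-organ Kp values
#'   to use verbatim.
#' @return a tibble with columns `organ`, `kp`, `source`; attribute
#'   `method` names the calculation scheme.
#' @export
#' @examples
#' kp <- partition_coefficients(read_compound("saxagliptin"),
#'                              load_physiology("rat"))
#' kp[kp$organ %in% c("adipose", "muscle"), ]
partition_coefficients <- function(cmp, phys, overrides = NULL) {
  stopifnot(inherits(cmp, "pbpk_compound"), inherits(phys, "pbpk_physiology"))
  org <- phys$organs
  need <- c("f_water", "f_lipid", "f_protein")
  if (any(!stats::complete.cases(org[need]))) {
    abort("missing tissue composition for at least one organ")
  }
  p <- 10^cmp$logd74
  denom <- tissue_affinity(p, KP_PLASMA["water"], KP_PLASMA["lipid"],
                           KP_PLASMA["protein"])
  kp <- tissue_affinity(p, org$f_water, org$f_lipid, org$f_protein) / denom
  out <- tibble(organ = org$organ, kp = as.numeric(kp), source = "calculated")
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), out$organ)
    if (length(bad)) abort(sprintf("Kp override for unknown organ(s): %s",
                                   paste(bad, collapse = ", ")))
    idx <- match(names(overrides), out$organ)
    out$kp[idx] <- as.numeric(overrides)
    out$source[idx] <- "override"
  }
  check_positive(out$kp, "kp")
  attr(out, "method") <- "tissue-composition (water/lipid/protein, logD7.4)"
  out
}

kp_erythrocyte <- function(cmp) {
  p <- 10^cmp$logd74
  denom <- tissue_affinity(p, KP_PLASMA["water"], KP_PLASMA["lipid"],
                           KP_PLASMA["protein"])
  as.numeric(tissue_affinity(p, KP_RBC_COMPOSITION["f_water"],
                             KP_RBC_COMPOSITION["f_lipid"],
                             KP_RBC_COMPOSITION["f_protein"]) / denom)
}

# dissolution ---------------------------------------------------------------

#' Fraction of an oral dose dissolved at time t
#'
#' Tablets dissolve along a Weibull curve anchored so that half the dose is
#' dissolved at `dissolution_time_min`:
#' `F(t) = 1 - exp(-ln(2) * (t / T50)^shape)`. Solutions are complete for
#' any `t > 0`.
#'
#' @param form a formulation spec (element of `compound$formulations`).
#' @param t_min time since administration, minutes (vectorized, `>= 0`).
#' @return dissolved fraction in `[0, 1]`.
#' @export
#' @examples
#' tb <- list(kind = "tablet", dissolution_shape = 0.68,
#'            dissolution_time_min = 120.5)
#' dissolved_fraction(tb, c(0, 120.5, 241))
dissolved_fraction <- function(form, t_min) {
  if (any(t_min < 0)) abort("`t_min` must be nonnegative")
  if (identical(form$kind, "solution")) {
    return(as.numeric(t_min > 0))
  }
  s <- form$dissolution_shape
  t50 <- form$dissolution_time_min
  check_positive(s, "dissolution_shape")
  check_positive(t50, "dissolution_time_min")
  1 - exp(-log(2) * (t_min / t50)^s)
}

# Weibull dissolution hazard (1/h), capped for numerical regularity near
# t = 0 when shape < 1. t_h is time since the oral dose, hours.
dissolution_hazard_per_h <- function(form, t_h, cap = 500) {
  if (identical(form$kind, "solution")) return(rep(cap, length(t_h)))
  s <- form$dissolution_shape
  t50_h <- form$dissolution_time_min / 60
  h <- ifelse(t_h <= 0, if (s < 1) cap else 0,
              log(2) * s * (t_h / t50_h)^(s - 1) / t50_h)
  pmin(h, cap)
}
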