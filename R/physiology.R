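#' Assemble a species physiology for whole-body PBPK simulation
#'
#' Builds the anatomical/physiological parameter set for a rat or human:
#' organ volumes, regional blood flows, sub-compartment fractions
#' (vascular, interstitial, intracellular), tissue composition (water,
#' lipid, protein) used for partition-coefficient calculation, gut-lumen
#' transit segments, and CYP enzyme abundance scaling factors
#' (microsomal protein per gram liver and reference enzyme concentrations
#' per mg microsomal protein). Values come from the bundled reference
#' tables (versioned CSVs under `extdata/physiology/`), are scaled
#' linearly to the requested body weight, and every scalar can be
#' overridden.
#'
#' The rat defaults carry 44.8 mg microsomal protein per g liver and a
#' CYP3A2 reference concentration of 101 pmol per mg microsomal protein.
#'
#' @param species `"rat"` or `"human"`.
#' @param body_weight body weight in kg (default: the bundled reference
#'   weight, 0.25 kg rat / 70 kg human).
#' @param overrides named list of replacement values using dotted keys,
#'   e.g. `list(mppgl = 44.8, "organ.liver.volume_ml" = 10)`. Scalar keys:
#'   `mppgl`, `hematocrit`, `cardiac_output_ml_min`, `blood_volume_ml`;
#'   organ keys: `organ.<name>.<column>`; gut keys: `gi.<segment>.<column>`;
#'   enzyme keys: `enzyme.<name>.ref_conc_pmol_per_mg`. Organ volumes and
#'   flows are overridden at the *reference* body weight and then scaled.
#'   If an organ `flow_frac` is overridden, the `rest` compartment flow is
#'   rebalanced so that venous return still equals cardiac output.
#' @return an object of class `pbpk_physiology`: a list with elements
#'   `species`, `body_weight`, `hematocrit`, `mppgl`,
#'   `cardiac_output_ml_h`, `organs` (tibble), `gi` (tibble), `enzymes`
#'   (tibble), `blood` (named volumes in mL) and `provenance` (tibble of
#'   every overridden parameter).
#' @export
#' @examples
#' rat <- load_physiology("rat", 0.25)
#' rat$mppgl
load_physiology <- function(species, body_weight = NULL, overrides = list()) {
  if (!is.character(species) || length(species) != 1 ||
      !species %in% c("rat", "human")) {
    abort("`species` must be \"rat\" or \"human\"")
  }
  sp <- read_csv_strict(extdata("physiology", "species.csv"))
  sp <- sp[sp$species == species, ]
  organs <- read_csv_strict(extdata("physiology",
                                    paste0("organs_", species, ".csv")))
  gi <- read_csv_strict(extdata("physiology", "gi.csv"))
  gi <- gi[gi$species == species, setdiff(names(gi), "species")]
  enz <- read_csv_strict(extdata("physiology", "enzymes.csv"))
  enz <- enz[enz$species == species, setdiff(names(enz), "species")]

  body_weight <- body_weight %||% sp$body_weight_ref_kg
  check_positive(body_weight, "body_weight")

  scalars <- list(
    mppgl = sp$mppgl_mg_per_g,
    hematocrit = sp$hematocrit,
    cardiac_output_ml_min = sp$cardiac_output_ml_min,
    blood_volume_ml = sp$blood_volume_ml,
    arterial_frac = sp$arterial_frac
  )

  prov <- tibble(parameter = character(), value = numeric(),
                 source = character())
  flow_overridden <- FALSE

  for (key in names(overrides)) {
    val <- overrides[[key]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val)) {
      abort(sprintf("override `%s` must be a single finite number", key))
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (!key %in% names(scalars)) {
        abort(sprintf("unknown physiology parameter `%s`", key))
      }
      if (val <= 0 && key != "arterial_frac") {
        abort(sprintf("override `%s` must be positive", key))
      }
      scalars[[key]] <- val
    } else if (parts[1] == "organ" && length(parts) == 3) {
      if (!parts[2] %in% organs$organ) {
        abort(sprintf("unknown organ `%s`", parts[2]))
      }
      if (!parts[3] %in% setdiff(names(organs), "organ")) {
        abort(sprintf("unknown organ parameter `%s`", parts[3]))
      }
      if (val < 0) abort(sprintf("override `%s` must be nonnegative", key))
      organs[organs$organ == parts[2], parts[3]] <- val
      if (parts[3] == "flow_frac") flow_overridden <- TRUE
    } else if (parts[1] == "gi" && length(parts) == 3) {
      if (!parts[2] %in% gi$segment) {
        abort(sprintf("unknown gut segment `%s`", parts[2]))
      }
      if (!parts[3] %in% setdiff(names(gi), "segment")) {
        abort(sprintf("unknown gut parameter `%s`", parts[3]))
      }
      if (val < 0) abort(sprintf("override `%s` must be nonnegative", key))
      gi[gi$segment == parts[2], parts[3]] <- val
    } else if (parts[1] == "enzyme" && length(parts) == 3) {
      if (!parts[2] %in% enz$enzyme) {
        abort(sprintf("unknown enzyme `%s`", parts[2]))
      }
      if (val <= 0) abort(sprintf("override `%s` must be positive", key))
      enz[enz$enzyme == parts[2], "ref_conc_pmol_per_mg"] <- val
    } else {
      abort(sprintf("cannot resolve override key `%s`", key))
    }
    prov <- bind_rows(prov, tibble(parameter = key, value = val,
                                   source = "override"))
  }

  # rebalance venous return through the rest-of-body compartment
  if (flow_overridden) {
    others <- sum(organs$flow_frac[!organs$organ %in% c("lung", "rest")])
    if (others >= 1) {
      abort("organ flow fractions exceed cardiac output; reduce an override")
    }
    organs$flow_frac[organs$organ == "rest"] <- 1 - others
  }

  fsum <- sum(organs$flow_frac[organs$organ != "lung"])
  stopifnot(abs(fsum - 1) < 1e-9)
  bad <- organs$f_vascular + organs$f_interstitial
  if (any(bad >= 1)) {
    abort("vascular + interstitial volume fractions must stay below 1")
  }

  scale <- body_weight / sp$body_weight_ref_kg
  organs$volume_ml <- organs$volume_ml * scale
  co_ml_h <- scalars$cardiac_output_ml_min * 60 * scale
  organs$flow_ml_h <- ifelse(organs$organ == "lung", co_ml_h,
                             organs$flow_frac * co_ml_h)
  gi$lumen_volume_ml <- gi$lumen_volume_ml * scale
  gi$surface_area_cm2 <- gi$surface_area_cm2 * scale
  blood_ml <- scalars$blood_volume_ml * scale
  hct <- scalars$hematocrit
  blood <- c(
    arterial_plasma = blood_ml * scalars$arterial_frac * (1 - hct),
    arterial_rbc = blood_ml * scalars$arterial_frac * hct,
    venous_plasma = blood_ml * (1 - scalars$arterial_frac) * (1 - hct),
    venous_rbc = blood_ml * (1 - scalars$arterial_frac) * hct
  )

  check_positive(organs$volume_ml, "organ volumes")
  check_positive(organs$flow_ml_h, "organ blood flows")
  check_nonnegative(organs$cyp3a_expr, "enzyme relative expression")

  structure(list(
    species = species,
    body_weight = body_weight,
    reference_body_weight = sp$body_weight_ref_kg,
    hematocrit = hct,
    mppgl = scalars$mppgl,
    cardiac_output_ml_h = co_ml_h,
    organs = organs,
    gi = gi,
    enzymes = as_tibble(enz),
    blood = blood,
    provenance = prov
  ), class = "pbpk_physiology")
}

#' @export
print.pbpk_physiology <- function(x, ...) {
  cat(sprintf("<pbpk_physiology> %s, %.3g kg, CO %.3g L/h, %d organs\n",
              x$species, x$body_weight, x$cardiac_output_ml_h / 1000,
              nrow(x$organs)))
  cat(sprintf("  MPPGL %.3g mg/g liver; enzymes: %s\n", x$mppgl,
              paste(sprintf("%s=%.3g pmol/mg", x$enzymes$enzyme,
                            x$enzymes$ref_conc_pmol_per_mg),
                    collapse = ", ")))
  if (nrow(x$provenance)) {
    cat(sprintf("  %d override(s)\n", nrow(x$provenance)))
  }
  invisible(x)
}

#' Amount of a CYP enzyme in an organ
#'
#' Abundance in pmol, computed as the reference microsomal concentration
#' (pmol per mg microsomal protein) times microsomal protein per gram of
#' tissue (MPPGL) times organ mass (g, unit tissue density) times the
#' organ's relative expression level (liver = 1).
#'
#' @param phys a [load_physiology()] object.
#' @param enzyme enzyme identifier present in `phys$enzymes`.
#' @param organ organ name present in `phys$organs`.
#' @return amount of enzyme in pmol (0 where relative expression is 0).
#' @export
#' @examples
#' rat <- load_physiology("rat")
#' organ_enzyme_abundance(rat, "CYP3A2", "liver")
organ_enzyme_abundance <- function(phys, enzyme, organ) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  if (!enzyme %in% phys$enzymes$enzyme) {
    abort(sprintf("unknown enzyme `%s` for species %s", enzyme, phys$species))
  }
  if (!organ %in% phys$organs$organ) {
    abort(sprintf("unknown organ `%s`", organ))
  }
  ref <- phys$enzymes$ref_conc_pmol_per_mg[phys$enzymes$enzyme == enzyme]
  row <- phys$organs[phys$organs$organ == organ, ]
  ref * phys$mppgl * row$volume_ml * row$cyp3a_expr
}

#' Serialize a physiology to YAML
#'
#' The written file is fully self-contained and [read_physiology()] restores
#' an identical object (lossless round trip).
#'
#' @param phys a `pbpk_physiology` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_physiology <- function(phys, path) {
  stopifnot(inherits(phys, "pbpk_physiology"))
  out <- list(
    species = phys$species,
    body_weight = phys$body_weight,
    reference_body_weight = phys$reference_body_weight,
    hematocrit = phys$hematocrit,
    mppgl = phys$mppgl,
    cardiac_output_ml_h = phys$cardiac_output_ml_h,
    organs = as.list(phys$organs),
    gi = as.list(phys$gi),
    enzymes = as.list(phys$enzymes),
    blood = as.list(phys$blood),
    provenance = as.list(phys$provenance)
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Read a physiology written by [write_physiology()]
#' @param path file path.
#' @return a `pbpk_physiology` object.
#' @export
read_physiology <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(list(
    species = raw$species,
    body_weight = raw$body_weight,
    reference_body_weight = raw$reference_body_weight,
    hematocrit = raw$hematocrit,
    mppgl = raw$mppgl,
    cardiac_output_ml_h = raw$cardiac_output_ml_h,
    organs = as_tibble(raw$organs),
    gi = as_tibble(raw$gi),
    enzymes = as_tibble(raw$enzymes),
    blood = unlist(raw$blood),
    provenance = if (length(raw$provenance$parameter)) {
      as_tibble(raw$provenance)
    } else {
      tibble(parameter = character(), value = numeric(), source = character())
    }
  ), class = "pbpk_physiology")
}
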