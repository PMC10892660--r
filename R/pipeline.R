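# Configuration-driven pipeline: physiology -> compounds -> single-drug
# simulation -> DDI co-simulation -> NCA -> evaluation -> sensitivity,
# with CSV/JSON artifacts and a run manifest.

#' Write a plasma-profile CSV
#' @param profile tibble with `time_h`, `conc_ng_per_ml`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}

#' Write the tidy state trajectories of a simulation
#'
#' Columns: `time_h`, `compound`, `compartment`, `amount_nmol`.
#' @param sim a `pbpk_sim`.
#' @param path output path.
#' @param thin keep every `thin`-th output time (default 10) to keep
#'   files reviewable.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path, thin = 10) {
  d <- tidy(sim) |>
    mutate(compound = sim$metadata$compound, .after = "time_h")
  keep_t <- unique(sim$time_h[seq(1, length(sim$time_h), by = thin)])
  utils::write.csv(d[d$time_h %in% keep_t, ], path, row.names = FALSE)
  invisible(path)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a YAML path or a list")
  required <- c("victim", "species", "victim_dose")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(sprintf("config is missing: %s", paste(missing, collapse = ", ")))
  }
  config
}

resolve_compound <- function(x) {
  if (inherits(x, "pbpk_compound")) return(x)
  read_compound(x)
}

#' Run the full modeling pipeline from a configuration
#'
#' Executes the stages in order — physiology assembly, compound loading,
#' victim-alone simulation, DDI co-simulation (when a perpetrator is
#' configured), NCA of the simulated profiles, evaluation against
#' observed data (when provided; otherwise skipped with a notice), and a
#' sensitivity scan (when parameters are listed) — writing CSV/JSON
#' artifacts and a JSON run manifest to `out_dir`. Reruns with the same
#' configuration and seed are bit-identical for the deterministic stages.
#'
#' @param config YAML file path or list. Keys: `victim` (compound YAML
#'   path or bundled name), optional `perpetrator`, `species`,
#'   `victim_dose`, optional `perp_dose`, `per_kg`, `route`,
#'   `victim_formulation`, `perp_formulation`, `duration_h`,
#'   `body_weight`, `observed_profile_csv`, `sensitivity_parameters`
#'   (list of paths), `population` (`n_subjects`, `cv`, `level`),
#'   `solver`, `seed`.
#' @param out_dir output directory (created if absent); temporary
#'   directory when `NULL`.
#' @param seed overrides `config$seed` (default 1 when neither is set).
#' @return invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_pipeline_config(config)
  seed <- seed %||% cfg$seed %||% 1
  out_dir <- out_dir %||% file.path(tempdir(), "pbpkddi-run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stages <- list()
  results <- list()
  note <- function(stage, status, detail = NULL) {
    message(sprintf("[%s] %s%s", stage, status,
                    if (is.null(detail)) "" else paste0(" - ", detail)))
    stages[[length(stages) + 1]] <<- list(stage = stage, status = status,
                                          detail = detail)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", stage, conditionMessage(e)))
    })
    note(stage, "completed",
         sprintf("%.2f s", as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  phys <- run_stage("physiology", load_physiology(
    cfg$species, cfg$body_weight,
    cfg$physiology_overrides %||% list()))

  cmps <- run_stage("compound", {
    v <- resolve_compound(cfg$victim)
    p <- if (!is.null(cfg$perpetrator)) resolve_compound(cfg$perpetrator)
    list(victim = v, perpetrator = p)
  })

  vic_sc <- pbpk_scenario(
    cmps$victim, cfg$species, cfg$victim_dose,
    per_kg = cfg$per_kg %||% TRUE, route = cfg$route %||% "oral",
    formulation = cfg$victim_formulation %||% "solution",
    body_weight = cfg$body_weight, duration_h = cfg$duration_h %||% 24,
    physiology_overrides = cfg$physiology_overrides %||% list(),
    solver = cfg$solver %||% list())

  alone <- run_stage("simulate_alone", simulate_scenario(vic_sc))
  write_profile_csv(alone$profile,
                    file.path(out_dir, "victim_alone_profile.csv"))
  write_sim_csv(alone, file.path(out_dir, "victim_alone_states.csv"))

  ddi <- NULL
  if (!is.null(cmps$perpetrator)) {
    ddi_sc <- ddi_scenario(
      cmps$victim, cmps$perpetrator, cfg$species,
      victim_dose = cfg$victim_dose, perp_dose = cfg$perp_dose %||% 0,
      per_kg = cfg$per_kg %||% TRUE,
      victim_formulation = cfg$victim_formulation %||% "solution",
      perp_formulation = cfg$perp_formulation %||% "solution",
      route = cfg$route %||% "oral", body_weight = cfg$body_weight,
      duration_h = cfg$duration_h %||% 24,
      inhibitor_source = cfg$inhibitor_source %||%
        "liver_intracellular_unbound",
      physiology_overrides = cfg$physiology_overrides %||% list(),
      solver = cfg$solver %||% list())
    ddi <- run_stage("simulate_ddi", simulate_ddi(ddi_sc))
    write_profile_csv(ddi$combo_profile,
                      file.path(out_dir, "victim_coadministered_profile.csv"))
    write_profile_csv(ddi$perp_profile,
                      file.path(out_dir, "perpetrator_profile.csv"))
    jsonlite::write_json(
      list(pk_alone = as.list(ddi$pk_alone[1, ]),
           pk_combo = as.list(ddi$pk_combo[1, ]),
           ddi_auc_ratio = ddi$ratios$ddi_auc_ratio,
           ddi_cmax_ratio = ddi$ratios$ddi_cmax_ratio,
           seed = seed),
      file.path(out_dir, "ddi_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    note("simulate_ddi", "skipped", "no perpetrator configured")
  }

  nca <- run_stage("nca", {
    tabs <- list(victim_alone = nca_single(
      alone$profile, dose = cfg$victim_dose,
      dose_per_kg = cfg$per_kg %||% TRUE))
    if (!is.null(ddi)) {
      tabs$victim_coadministered <- ddi$pk_combo
    }
    bind_rows(tabs, .id = "arm")
  })
  utils::write.csv(nca, file.path(out_dir, "nca_parameters.csv"),
                   row.names = FALSE)

  evalrep <- NULL
  if (!is.null(cfg$observed_profile_csv)) {
    evalrep <- run_stage("evaluate", {
      obs <- read_profile_csv(cfg$observed_profile_csv)
      pred <- alone$profile
      obs_pos <- obs[obs$conc_ng_per_ml > 0, ]
      pred_at <- tibble(
        time_h = obs_pos$time_h,
        conc_ng_per_ml = sample_profile(pred, obs_pos$time_h))
      rep <- evaluation_report(observed_profile = obs_pos,
                               predicted_profile = pred_at)
      jsonlite::write_json(
        list(mrd = rep$mrd, pass_mrd = rep$pass_mrd, seed = seed),
        file.path(out_dir, "evaluation.json"),
        auto_unbox = TRUE, digits = NA)
      rep
    })
  } else {
    note("evaluate", "skipped", "no observed data configured")
  }

  sens <- NULL
  if (!is.null(cfg$sensitivity_parameters) && !is.null(ddi)) {
    sens <- run_stage("sensitivity", sensitivity_scan(
      ddi$scenario, unlist(cfg$sensitivity_parameters),
      delta = cfg$sensitivity_delta %||% 0.1))
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  } else {
    note("sensitivity", "skipped", "no parameter list configured")
  }

  pop <- NULL
  if (!is.null(cfg$population)) {
    pop <- run_stage("population", {
      spec <- cfg$population
      spec$cv <- unlist(spec$cv)
      spec$seed <- spec$seed %||% seed
      pi <- prediction_interval(if (!is.null(ddi)) ddi$scenario else vic_sc,
                                spec)
      utils::write.csv(pi, file.path(out_dir, "prediction_interval.csv"),
                       row.names = FALSE)
      pi
    })
  } else {
    note("population", "skipped", "no population spec configured")
  }

  manifest <- list(
    package = "pbpkddi",
    version = as.character(utils::packageVersion("pbpkddi")),
    seed = seed,
    species = cfg$species,
    victim = cmps$victim$name,
    perpetrator = if (!is.null(cmps$perpetrator)) cmps$perpetrator$name,
    stages = stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(physiology = phys, compounds = cmps, alone = alone,
                 ddi = ddi, nca = nca, evaluation = evalrep,
                 sensitivity = sens, population = pop,
                 manifest = manifest, out_dir = out_dir))
}
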