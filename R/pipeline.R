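#' Build a validated run configuration
#'
#' Central configuration for [run_pipeline()]: input paths, thresholds and
#' modes for every stage. Thresholds are validated against their admissible
#' ranges up front so a bad configuration fails before any work is done.
#'
#' @param out_dir Output directory for stage results and the manifest.
#' @param plates,control_plates,key Paths to the double-mutant plate table,
#'   control plate table and array key (screen stage; all three required).
#' @param reference Reference colony size defining fitness 1 (required for
#'   the screen stage).
#' @param spots,od,psms,dose_spots Optional paths enabling the validation,
#'   growth, mistranslation and dose-response stages.
#' @param eps_threshold Negative interaction-score threshold (< 0, default
#'   -0.2).
#' @param q_threshold BH-adjusted p-value threshold (default 0.05).
#' @param theta Spot-validation margin (default 0.9).
#' @param fdr PSM-level q-value cutoff (default 0.01).
#' @param counting PSM counting mode, `"spectral"` or `"unique"`.
#' @param normalize_mode Plate normalization mode (see [normalize_plates()]).
#' @param wt_strain Wild-type strain for the dose-response stage.
#' @param constants Dose-response classification constants
#'   (see [dose_response_constants()]).
#' @param w_query Optional known query fitness W_B.
#' @param seed Seed for all stochastic steps (default 1729).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       plates = NULL, control_plates = NULL, key = NULL,
                       reference = NULL,
                       spots = NULL, od = NULL, psms = NULL, dose_spots = NULL,
                       eps_threshold = -0.2, q_threshold = 0.05,
                       theta = 0.9, fdr = 0.01,
                       counting = "spectral",
                       normalize_mode = "medpolish",
                       wt_strain = "BY4742",
                       constants = dose_response_constants(),
                       w_query = NULL,
                       seed = 1729) {
  if (eps_threshold >= 0) abort_bad_input("eps_threshold must be negative")
  if (q_threshold <= 0 || q_threshold >= 1) {
    abort_bad_input("q_threshold must lie in (0, 1)")
  }
  if (theta <= 0) abort_bad_input("theta must be positive")
  if (fdr < 0 || fdr > 1) abort_bad_input("fdr must lie in [0, 1]")
  if (!counting %in% c("spectral", "unique")) {
    abort_bad_input("counting must be 'spectral' or 'unique'")
  }
  if (!is.null(reference) && reference <= 0) {
    abort_bad_input("reference colony size must be positive")
  }
  structure(
    list(
      out_dir = out_dir, plates = plates, control_plates = control_plates,
      key = key, reference = reference, spots = spots, od = od, psms = psms,
      dose_spots = dose_spots, eps_threshold = eps_threshold,
      q_threshold = q_threshold, theta = theta, fdr = fdr,
      counting = counting, normalize_mode = normalize_mode,
      wt_strain = wt_strain, constants = constants, w_query = w_query,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' Reads a declarative configuration file whose keys mirror the arguments of
#' [run_config()] and validates it. The configuration round-trips losslessly
#' through its on-disk form.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_bad_input(
      "unknown config key(s): ", paste(unknown, collapse = ", ")
    )
  }
  if (!is.null(raw$constants)) {
    raw$constants <- do.call(dose_response_constants, raw$constants)
  }
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the screen-to-dose-response pipeline
#'
#' Executes the analysis stages in order on the inputs named in the
#' configuration, persisting every intermediate as TSV under
#' `cfg$out_dir` together with a provenance manifest (configuration hash,
#' seed, package version, per-stage record counts). The screen stage
#' (normalize, fitness, interaction scores, calls) is required; validation,
#' growth, mistranslation and dose-response stages run when their inputs are
#' configured. No stage mutates its inputs, and reruns with the same
#' configuration and seed produce an identical manifest hash.
#'
#' @param cfg A [run_config()] (or path to a YAML configuration).
#' @return Invisibly, a list with each stage's result and the manifest.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$plates) || is.null(cfg$control_plates) || is.null(cfg$key) ||
    is.null(cfg$reference)) {
    abort_bad_input(
      "screen stage requires plates, control_plates, key and reference"
    )
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  results <- list()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      rlang::abort(
        paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        parent = e
      )
    })
  }

  pipeline_log("config", sprintf(
    "eps<%s, q<%s, theta=%s, fdr=%s, seed=%d",
    cfg$eps_threshold, cfg$q_threshold, cfg$theta, cfg$fdr, cfg$seed
  ))

  results$hits <- run_stage("screen", function() {
    doubles <- read_plate_table(cfg$plates)
    controls <- read_plate_table(cfg$control_plates)
    key <- read_array_key(cfg$key)
    hits <- score_screen(
      doubles, controls, key,
      reference = cfg$reference,
      mode = cfg$normalize_mode, w_query = cfg$w_query,
      eps_threshold = cfg$eps_threshold, q_threshold = cfg$q_threshold
    )
    write_interaction_table(hits, file.path(cfg$out_dir, "hits.tsv"))
    stages$screen <<- c(n_in = nrow(doubles), n_out = nrow(hits))
    pipeline_log("screen", sprintf(
      "%d alleles scored, %d negative, %d positive calls",
      nrow(hits), sum(hits$call == "negative"), sum(hits$call == "positive")
    ))
    hits
  })

  if (!is.null(cfg$spots)) {
    results$validation <- run_stage("validate", function() {
      spots <- readr::read_tsv(cfg$spots, show_col_types = FALSE)
      val <- validate_hits(spots, theta = cfg$theta)
      readr::write_tsv(val, file.path(cfg$out_dir, "validated.tsv"))
      stages$validate <<- c(n_in = nrow(spots), n_out = nrow(val))
      pipeline_log("validate", sprintf(
        "%d strains, %d validated", nrow(val), sum(val$validated)
      ))
      val
    })
  }

  if (!is.null(cfg$od)) {
    results$growth <- run_stage("growth", function() {
      od <- read_od_table(cfg$od)
      fits <- fit_growth_curves(od)
      readr::write_tsv(fits, file.path(cfg$out_dir, "growth_fits.tsv"))
      stages$growth <<- c(n_in = nrow(od), n_out = nrow(fits))
      pipeline_log("growth", sprintf(
        "%d curves fitted, %d converged", nrow(fits), sum(fits$converged)
      ))
      fits
    })
  }

  if (!is.null(cfg$psms)) {
    results$mistranslation <- run_stage("mistrans", function() {
      psms <- read_psm_table(cfg$psms)
      freq <- mistranslation_frequency(
        psms,
        fdr = cfg$fdr, counting = cfg$counting
      )
      readr::write_tsv(freq, file.path(cfg$out_dir, "mistranslation.tsv"))
      stages$mistrans <<- c(n_in = nrow(psms), n_out = nrow(freq))
      pipeline_log("mistrans", sprintf(
        "frequency %.2f%%", freq$frequency_pct[1]
      ))
      freq
    })
  }

  if (!is.null(cfg$dose_spots)) {
    results$dose_response <- run_stage("doseresp", function() {
      spots <- read_spot_table(cfg$dose_spots)
      prof <- normalized_growth(spots, seed = cfg$seed)
      rel <- relative_synthetic_effect(prof, wt_strain = cfg$wt_strain)
      cls <- classify_profiles(rel, constants = cfg$constants)
      readr::write_tsv(
        dplyr::select(prof, -"rep_pct"),
        file.path(cfg$out_dir, "dose_profiles.tsv")
      )
      readr::write_tsv(cls, file.path(cfg$out_dir, "dose_categories.tsv"))
      stages$doseresp <<- c(n_in = nrow(spots), n_out = nrow(cls))
      pipeline_log("doseresp", sprintf(
        "%d strains classified (%s)",
        nrow(cls),
        paste(sprintf("%s: %d", names(table(cls$category)), table(cls$category)),
          collapse = ", "
        )
      ))
      cls
    })
  }

  manifest <- list(
    package = "sgamist",
    version = as.character(utils::packageVersion("sgamist")),
    config = unclass(cfg),
    config_hash = rlang::hash(unclass(cfg)),
    seed = cfg$seed,
    stages = stages
  )
  manifest$manifest_hash <- rlang::hash(manifest)
  jsonlite::write_json(
    manifest, file.path(cfg$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  results$manifest <- manifest
  invisible(results)
}
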