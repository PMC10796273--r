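stage_exit_codes <- c(config = 2L, kinetics = 3L, qbet = 4L, spectral = 5L,
                      io = 6L)

abort_stage <- function(stage, msg, parent = NULL) {
  abort(msg, class = c(paste0("qbetr_stage_", stage), "qbetr_stage_error",
                       "qbetr_error"),
        stage = stage, exit_code = stage_exit_codes[[stage]],
        parent = parent)
}

#' Build and validate a full-pipeline run configuration
#'
#' A configuration is a named list; this constructor fills defaults and
#' validates it. Accepts either individual arguments or, via
#' [read_run_config()], a YAML/JSON file with the same field names.
#'
#' @param stages Character vector of stages to run, a subset of
#'   `c("synthetic", "kinetics", "qbet", "spectral", "feasibility")`.
#' @param seed Integer seed; required whenever the synthetic stage is
#'   enabled.
#' @param D_coeff Diffusion coefficient for the rate-constant equation,
#'   cm^2 s^-1 (required when kinetics runs).
#' @param n_electrons Electrons transferred.
#' @param temperature_K Temperature, kelvin.
#' @param frequency_Hz Stimulation frequency for the feasibility bound;
#'   default 3e6 (the 3 MHz drive).
#' @param alpha_ct Optional transfer coefficient override for kinetics.
#' @param k0 Explicit rate constant (cm s^-1) for feasibility when the
#'   kinetics stage is disabled.
#' @param feasibility_linker_kda Linker mass whose length the feasibility
#'   verdict is compared against.
#' @param thresholds List: `dip_prominence` (a.u.), `soret_shift_nm`.
#' @param length_convention Arguments for [linker_length_from_mw()].
#' @param synthetic List of generator settings used when `"synthetic"` is
#'   enabled: `cv` ([cv_sim_params()] arguments plus `rates`), `metabolic`
#'   ([metabolic_sim_params()] arguments), `spectra` (logical or
#'   [spectrum_sim_params()] arguments).
#' @param inputs List of file paths used when a stage consumes recorded
#'   data: `cv_manifest`, `metabolic_csv`, `spectra` (named list with
#'   `minuend_csv`/`subtrahend_csv` and optionally `soret_pre_csv`/
#'   `soret_post_csv`). Paths must exist at validation time.
#' @param output_dir Where [write_report()] puts files.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(stages = c("synthetic", "kinetics", "qbet",
                                  "spectral", "feasibility"),
                       seed = NULL,
                       D_coeff = 1e-6,
                       n_electrons = 1L,
                       temperature_K = 298.15,
                       frequency_Hz = 3e6,
                       alpha_ct = NULL,
                       k0 = NULL,
                       feasibility_linker_kda = 2,
                       thresholds = list(),
                       length_convention = list(),
                       synthetic = list(),
                       inputs = list(),
                       output_dir = tempfile("qbet_report_")) {
  all_stages <- c("synthetic", "kinetics", "qbet", "spectral", "feasibility")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L) {
    abort_stage("config", sprintf("Unknown stage(s): %s.",
                                  paste(bad, collapse = ", ")))
  }
  if ("synthetic" %in% stages && is.null(seed)) {
    abort_stage("config",
                "`seed` is required when the synthetic stage is enabled.")
  }
  thresholds <- modifyList(list(dip_prominence = 0.02, soret_shift_nm = 2),
                           thresholds)
  for (p in unlist(inputs)) {
    if (is.character(p) && !file.exists(p)) {
      abort_stage("config", sprintf("Configured input does not exist: %s", p))
    }
  }
  if ("kinetics" %in% stages && !"synthetic" %in% stages &&
      is.null(inputs$cv_manifest)) {
    abort_stage("config",
                "Kinetics without synthesis needs `inputs$cv_manifest`.")
  }
  if ("qbet" %in% stages && !"synthetic" %in% stages &&
      is.null(inputs$metabolic_csv)) {
    abort_stage("config",
                "Metabolic modelling without synthesis needs `inputs$metabolic_csv`.")
  }
  if ("feasibility" %in% stages && !"kinetics" %in% stages && is.null(k0)) {
    abort_stage("config",
                "Feasibility without kinetics needs an explicit `k0`.")
  }
  structure(
    list(stages = stages, seed = seed, D_coeff = D_coeff,
         n_electrons = as.integer(n_electrons),
         temperature_K = temperature_K, frequency_Hz = frequency_Hz,
         alpha_ct = alpha_ct, k0 = k0,
         feasibility_linker_kda = feasibility_linker_kda,
         thresholds = thresholds, length_convention = length_convention,
         synthetic = synthetic, inputs = inputs, output_dir = output_dir),
    class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys are
#'   [run_config()] arguments.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_stage("config", sprintf("Config file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in order (synthesis, kinetics, metabolic/
#' tunnelling modelling, spectral analysis, feasibility), threading the mean
#' rate constant from kinetics into the feasibility bound when both run.
#' Identical configurations and seed give identical reports apart from the
#' provenance timestamp. A stage failure aborts with a classed condition
#' carrying the stage name and its documented exit code; stages already
#' completed are kept in the partial bundle attached to the condition as
#' `failed_at` marker plus results.
#'
#' @param config A [run_config()].
#' @return A list of class `"qbet_report"` with elements `kinetics`,
#'   `charging`, `tunnelling`, `feasibility`, `spectral` (each either a
#'   result or `list(status = "skipped")`) and `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bundle <- list(kinetics = list(status = "skipped"),
                 charging = list(status = "skipped"),
                 tunnelling = list(status = "skipped"),
                 feasibility = list(status = "skipped"),
                 spectral = list(status = "skipped"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      bundle$failed_at <<- stage
      abort_stage(stage, sprintf("Stage `%s` failed: %s", stage,
                                 conditionMessage(e)), parent = e)
    })
  }
  synth <- "synthetic" %in% config$stages
  warnings_log <- character()
  log_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- kinetics ----------------------------------------------------------
  k0_for_feasibility <- config$k0
  if ("kinetics" %in% config$stages) {
    res <- run_stage("kinetics", {
      study <- if (synth) {
        cv_cfg <- config$synthetic$cv %||% list()
        rates <- cv_cfg$rates %||% c(0.1, 0.2, 0.5, 1, 2)
        cv_cfg$rates <- NULL
        cv_cfg$temperature_K <- cv_cfg$temperature_K %||% config$temperature_K
        cv_cfg$seed <- cv_cfg$seed %||% config$seed
        params <- do.call(cv_sim_params, cv_cfg)
        simulate_scan_rate_study(params, rates)
      } else {
        read_scan_rate_study(config$inputs$cv_manifest,
                             temperature_K = config$temperature_K)
      }
      log_warnings(analyze_study(study, D_coeff = config$D_coeff,
                                 n_electrons = config$n_electrons,
                                 alpha_ct = config$alpha_ct))
    })
    bundle$kinetics <- res
    k0_for_feasibility <- k0_for_feasibility %||% res$k0_mean
  }

  # --- metabolic / tunnelling -------------------------------------------
  if ("qbet" %in% config$stages) {
    bundle[c("charging", "tunnelling")] <- run_stage("qbet", {
      dat <- if (synth) {
        mb_cfg <- config$synthetic$metabolic %||% list()
        mb_cfg$seed <- mb_cfg$seed %||% (config$seed + 1000L)
        params <- do.call(metabolic_sim_params, mb_cfg)
        do.call(simulate_metabolic_dataset,
                c(list(params), config$length_convention))
      } else {
        read_metabolic_csv(config$inputs$metabolic_csv)
      }
      charging <- log_warnings(
        do.call(aggregate_charging_rates,
                c(list(dat), config$length_convention)))
      fit <- log_warnings(fit_barrier_decay(charging))
      list(charging = charging, tunnelling = fit)
    })
  }

  # --- spectral ----------------------------------------------------------
  if ("spectral" %in% config$stages) {
    bundle$spectral <- run_stage("spectral", {
      if (synth) {
        sp_seed <- config$seed + 2000L
        func <- simulate_spectrum(spectrum_sim_params(
          bands = default_scattering_bands(TRUE), noise_sd = 0.002,
          seed = sp_seed))
        bare <- simulate_spectrum(spectrum_sim_params(
          bands = default_scattering_bands(FALSE), noise_sd = 0.002,
          seed = sp_seed + 1L))
        ds <- difference_spectrum(bare, func)
        feats <- detect_quantized_features(
          ds, min_prominence = config$thresholds$dip_prominence,
          polarity = "dip")
        lspr <- peak_max(func, c(550, 800))
        list(status = "ok", features = feats, lspr_nm = lspr,
             redox_call = list(status = "skipped"))
      } else {
        sp <- config$inputs$spectra
        ds <- difference_spectrum(
          read_spectrum_csv(sp$minuend_csv, kind = "scattering"),
          read_spectrum_csv(sp$subtrahend_csv, kind = "scattering"))
        feats <- detect_quantized_features(
          ds, min_prominence = config$thresholds$dip_prominence,
          polarity = "dip")
        redox <- if (!is.null(sp$soret_pre_csv)) {
          log_warnings(soret_shift_call(
            read_spectrum_csv(sp$soret_pre_csv, kind = "absorbance"),
            read_spectrum_csv(sp$soret_post_csv, kind = "absorbance"),
            threshold = config$thresholds$soret_shift_nm))
        } else {
          list(status = "skipped")
        }
        list(status = "ok", features = feats, redox_call = redox)
      }
    })
  }

  # --- feasibility -------------------------------------------------------
  if ("feasibility" %in% config$stages) {
    bundle$feasibility <- run_stage("qbet", {
      hop <- max_hop_distance(k0_for_feasibility, config$frequency_Hz)
      L <- do.call(linker_length_from_mw,
                   c(list(config$feasibility_linker_kda),
                     config$length_convention))
      classical_feasibility(hop$d_max_nm, L, k0 = k0_for_feasibility,
                            frequency = config$frequency_Hz)
    })
  }

  bundle$provenance <- list(
    config = unclass(config)[setdiff(names(config), "output_dir")],
    seed = config$seed,
    version = as.character(packageVersion("qbetr")),
    warnings = warnings_log,
    timestamp = format(Sys.time(), tz = "UTC"))
  class(bundle) <- "qbet_report"
  bundle
}

serialize_report <- function(bundle) {
  strip <- function(x) {
    if (inherits(x, "kinetics_result") || inherits(x, "tunnelling_fit")) {
      x <- unclass(x)
      x$data <- NULL
      x$loglinear <- as.list(x$loglinear)
      lapply(x, strip)
    } else if (is.data.frame(x)) {
      lapply(as.list(as_tibble(x)), unname)
    } else if (is.list(x)) {
      lapply(x, strip)
    } else {
      x
    }
  }
  strip(unclass(bundle))
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (keys sorted, schema version embedded) plus CSV
#' extracts of the tabular stage results. Skipped stages appear in the JSON
#' as `{"status": "skipped"}`, never silently omitted.
#'
#' @param bundle A `qbet_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the JSON report.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "qbet_report"))
  ok <- tryCatch({
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    file.access(dir, mode = 2L) == 0L
  }, error = function(e) FALSE)
  if (!ok) {
    abort_stage("io", sprintf("Output directory not writable: %s", dir))
  }
  payload <- serialize_report(bundle)
  payload$schema_version <- "1"
  payload <- payload[order(names(payload))]
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (inherits(bundle$kinetics, "kinetics_result")) {
    readr::write_csv(bundle$kinetics$per_rate,
                     file.path(dir, "kinetics_per_rate.csv"))
  }
  if (is.data.frame(bundle$charging)) {
    readr::write_csv(as_tibble(bundle$charging),
                     file.path(dir, "charging_rates.csv"))
  }
  if (inherits(bundle$tunnelling, "tunnelling_fit")) {
    fit <- bundle$tunnelling
    L_grid <- seq(min(fit$data$linker_length_nm),
                  max(fit$data$linker_length_nm), length.out = 100)
    readr::write_csv(
      tibble(linker_length_nm = L_grid,
             r_d_fit = fit$beta * exp(-fit$alpha_loc * L_grid)),
      file.path(dir, "tunnelling_fit_curve.csv"))
  }
  if (is.list(bundle$spectral) && is.data.frame(bundle$spectral$features)) {
    readr::write_csv(as_tibble(bundle$spectral$features),
                     file.path(dir, "spectral_features.csv"))
  }
  invisible(json_path)
}

#' Re-read a written JSON report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The parsed report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort_stage("io", sprintf("Report not found: %s", path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}
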