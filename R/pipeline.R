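#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: either a synthetic
#' experiment to generate (`experiment`) or an existing trajectory CSV
#' (`input`), the log-log analysis options, and the fit options. Can be
#' written to / read from YAML and round-trips losslessly.
#'
#' @param experiment An [experiment_config()], or `NULL` when reading
#'   trajectories from `input`.
#' @param input Path to a trajectory CSV (used when `experiment` is NULL).
#' @param tol,window_frac Options for [classify_kinetics()].
#' @param n_starts,fit_seed,bounds Options for the constrained fits.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = NULL, input = NULL,
                            tol = 0.3, window_frac = 0.3,
                            n_starts = 10, fit_seed = 1,
                            bounds = list(mu = c(1e-4, 1), c = c(1e-16, 1e-6))) {
  if (is.null(experiment) && is.null(input)) {
    abort("supply either `experiment` (synthetic run) or `input` (trajectory CSV).")
  }
  if (!is.null(experiment)) stopifnot(inherits(experiment, "experiment_config"))
  structure(list(experiment = experiment, input = input,
                 tol = tol, window_frac = window_frac,
                 n_starts = n_starts, fit_seed = fit_seed, bounds = bounds),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [pipeline_config()] and
#' [experiment_config()]; an `experiment:` block with a `seed` is required
#' for synthetic runs, otherwise an `input:` path.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  experiment <- NULL
  if (!is.null(y$experiment)) {
    e <- y$experiment
    kp <- if (!is.null(e$mu) || !is.null(e$c)) {
      kinetic_params(mu = e$mu %||% 0.018, c = e$c %||% 4.7e-12)
    } else kinetic_params()
    experiment <- experiment_config(
      densities = if (!is.null(e$densities)) unlist(e$densities),
      glycerol_mM = if (!is.null(e$glycerol_mM)) unlist(e$glycerol_mM),
      schedule = if (!is.null(e$schedule)) unlist(e$schedule) else seq(0, 288, by = 12),
      replicates = e$replicates %||% 3L,
      target_colonies = if (!is.null(e$target_colonies)) unlist(e$target_colonies) else c(100, 200),
      biological_cv = e$biological_cv %||% 0.10,
      strain = e$strain %||% "wild-type",
      params = kp,
      rpos_rate = e$rpos_rate %||% 0.035,
      plated_volume_ml = e$plated_volume_ml %||% 0.1,
      counting_noise = e$counting_noise %||% TRUE,
      seed = e$seed)
  }
  pipeline_config(experiment = experiment, input = y$input,
                  tol = y$tol %||% 0.3, window_frac = y$window_frac %||% 0.3,
                  n_starts = y$n_starts %||% 10, fit_seed = y$fit_seed %||% 1,
                  bounds = if (!is.null(y$bounds)) {
                    list(mu = unlist(y$bounds$mu), c = unlist(y$bounds$c))
                  } else list(mu = c(1e-4, 1), c = c(1e-16, 1e-6)))
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(tol = config$tol, window_frac = config$window_frac,
            n_starts = config$n_starts, fit_seed = config$fit_seed,
            bounds = list(mu = config$bounds$mu, c = config$bounds$c))
  if (!is.null(config$input)) y$input <- config$input
  if (!is.null(config$experiment)) {
    e <- config$experiment
    y$experiment <- list(
      densities = as.list(setNames(as.numeric(e$densities), names(e$densities))),
      schedule = e$schedule, replicates = e$replicates,
      target_colonies = e$target_colonies, biological_cv = e$biological_cv,
      strain = e$strain, mu = e$params$mu, c = e$params$c,
      rpos_rate = e$rpos_rate, plated_volume_ml = e$plated_volume_ml,
      counting_noise = e$counting_noise, seed = e$seed)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full starvation-survival pipeline
#'
#' Simulate (or load) trajectories, run the per-culture log-log diagnostics,
#' fit the biphasic law per culture and globally, measure the density
#' scaling of the first-phase duration and coefficient, and write a report
#' bundle: `trajectories.csv` (plus `plate_counts.csv` when simulating),
#' `analysis.csv`, `fits.csv`, `summary.txt` and `summary.json`.
#'
#' @param config A [pipeline_config()] or a path to its YAML form.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with `trajectories`, `analysis`, `fits`
#'   (tibble), `global_fit` (`starve_fit`), `scaling` (tibble) and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  log_msg <- function(...) message("[starvekin] ", ...)

  t_start <- Sys.time()
  if (!is.null(config$experiment)) {
    log_msg("simulating ", length(config$experiment$densities),
            " culture(s), seed ", config$experiment$seed)
    ds <- generate_dataset(config$experiment)
    trajectories <- ds$trajectories
    paths$plate_counts <- file.path(out_dir, "plate_counts.csv")
    write_plate_counts(ds$counts, paths$plate_counts)
  } else {
    log_msg("reading trajectories from ", config$input)
    trajectories <- read_trajectories(config$input)
  }
  paths$trajectories <- file.path(out_dir, "trajectories.csv")
  write_trajectories(trajectories, paths$trajectories)

  log_msg("log-log analysis of ", dplyr::n_distinct(trajectories$density_label),
          " culture(s)")
  analysis <- analyze_trajectories(trajectories, tol = config$tol,
                                   window_frac = config$window_frac)
  paths$analysis <- file.path(out_dir, "analysis.csv")
  readr::write_csv(analysis, paths$analysis, progress = FALSE)

  log_msg("per-culture constrained fits")
  fits <- trajectories |>
    dplyr::group_by(.data$strain, .data$density_label, .data$n0) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_piecewise_constrained(df, n_starts = config$n_starts,
                                     fit_seed = config$fit_seed,
                                     bounds = config$bounds)
      tibble(mu = f$params$mu, c = f$params$c,
             mu_se = f$stderr$mu, c_se = f$stderr$c,
             t0 = f$t0, n1 = f$n1, sse_log = f$sse_log,
             n_points = f$n_points, classification = f$classification,
             converged = f$converged, fit_seed = config$fit_seed)
    }) |>
    dplyr::ungroup()
  paths$fits <- file.path(out_dir, "fits.csv")
  readr::write_csv(fits, paths$fits, progress = FALSE)

  n_cultures <- dplyr::n_distinct(trajectories$density_label)
  global_fit <- if (n_cultures >= 2L) {
    log_msg("global fit across ", n_cultures, " densities")
    fit_global(trajectories, n_starts = config$n_starts,
               fit_seed = config$fit_seed, bounds = config$bounds)
  } else NULL

  scaling <- NULL
  if (n_cultures >= 3L) {
    t0_pairs <- tibble(n0 = fits$n0, value = fits$t0)
    c2_pairs <- tibble(n0 = fits$n0, value = fits$c * fits$n0)
    scaling <- dplyr::bind_rows(
      dplyr::mutate(scaling_exponent(t0_pairs), quantity = "T0", .before = 1),
      dplyr::mutate(scaling_exponent(c2_pairs), quantity = "c2", .before = 1))
  }

  summary_list <- list(
    n_cultures = n_cultures,
    classification = setNames(as.list(analysis$classification), analysis$density_label),
    t0_hr = setNames(as.list(fits$t0), fits$density_label),
    scaling = if (!is.null(scaling)) {
      setNames(as.list(scaling$exponent), scaling$quantity)
    },
    global = if (!is.null(global_fit)) {
      list(mu = global_fit$params$mu, c = global_fit$params$c,
           sse_log = global_fit$sse_log, converged = global_fit$converged)
    },
    seed = if (!is.null(config$experiment)) config$experiment$seed,
    fit_seed = config$fit_seed)

  paths$summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_list, paths$summary_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  paths$summary_txt <- file.path(out_dir, "summary.txt")
  txt <- c(
    "starvation-survival pipeline summary",
    sprintf("cultures: %d", n_cultures),
    "per-culture classification:",
    sprintf("  %s (n0 = %.3g): %s, T0 = %.4g hr", analysis$density_label,
            analysis$n0, analysis$classification,
            fits$t0[match(analysis$density_label, fits$density_label)]),
    if (!is.null(scaling)) {
      sprintf("scaling exponent of %s vs N0: %.6f (se %.2g)",
              scaling$quantity, scaling$exponent, scaling$se)
    },
    if (!is.null(global_fit)) {
      sprintf("global fit: mu = %.6g hr^-1, c = %.6g ml*hr^-2 (sse_log %.4g, converged %s)",
              global_fit$params$mu, global_fit$params$c,
              global_fit$sse_log, global_fit$converged)
    })
  txt <- txt[!vapply(txt, is.null, logical(1))]
  writeLines(unlist(txt), paths$summary_txt)
  log_msg("done in ",
          sprintf("%.1f", as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
          " s")

  invisible(list(trajectories = trajectories, analysis = analysis, fits = fits,
                 global_fit = global_fit, scaling = scaling, paths = paths))
}
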