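#' Configuration for a synthetic starvation plate-count experiment
#'
#' Describes one simulated starvation experiment: a set of batch cultures
#' arrested at the given densities, sampled on a common schedule and measured
#' by serial-dilution spread plating. Defaults mirror the glycerol-starvation
#' study design: sampling every 12 h over 12 days, 3 replicate plates per
#' time point, dilutions chosen to land 100-200 colonies per plate.
#'
#' @param densities Arrest densities, cells/ml (positive). Alternatively pass
#'   `glycerol_mM` and densities are derived via [density_from_glycerol()].
#' @param glycerol_mM Optional initial glycerol concentrations, mM; converted
#'   to densities when `densities` is missing.
#' @param schedule Sampling times, hr: non-empty, non-negative, strictly
#'   increasing. Default `seq(0, 288, by = 12)`.
#' @param replicates Plates per (culture, time). Default 3.
#' @param target_colonies Acceptable colonies-per-plate band, length 2.
#'   Default `c(100, 200)`.
#' @param biological_cv Lognormal coefficient of variation of the true
#'   density shared by all replicates of a (culture, time). Default 0.10.
#'   Must be in `[0, 1)`.
#' @param strain `"wild-type"` (biphasic law) or `"delta-rpoS"` (single
#'   exponential).
#' @param params [kinetic_params()] used for wild-type cultures.
#' @param rpos_rate Decay rate (hr^-1) for `"delta-rpoS"` cultures.
#'   Default 0.035.
#' @param plated_volume_ml Volume spread per plate, ml. Default 0.1.
#' @param counting_noise If `TRUE` (default) colony counts are Poisson draws
#'   at the diluted expectation; if `FALSE` the expectation itself is recorded
#'   (a noise-free diagnostic mode in which, with `biological_cv = 0`,
#'   generated trajectories pass through the model exactly).
#' @param seed Integer RNG seed; mandatory, no hidden global state.
#'
#' @return An object of class `experiment_config`.
#' @export
#' @examples
#' cfg <- experiment_config(densities = c(9e6, 7e8), seed = 1)
experiment_config <- function(densities = NULL,
                              glycerol_mM = NULL,
                              schedule = seq(0, 288, by = 12),
                              replicates = 3L,
                              target_colonies = c(100, 200),
                              biological_cv = 0.10,
                              strain = c("wild-type", "delta-rpoS"),
                              params = kinetic_params(),
                              rpos_rate = 0.035,
                              plated_volume_ml = 0.1,
                              counting_noise = TRUE,
                              seed) {
  strain <- match.arg(strain)
  if (is.null(densities)) {
    if (is.null(glycerol_mM)) abort("Supply `densities` or `glycerol_mM`.")
    densities <- density_from_glycerol(glycerol_mM)
    names(densities) <- paste0(format(glycerol_mM, trim = TRUE), "mM")
  }
  if (length(densities) == 0L) abort("`densities` must be non-empty.")
  check_nonnegative(densities, "densities")
  if (any(densities <= 0)) abort("`densities` must all be positive.")
  if (is.null(names(densities))) {
    names(densities) <- paste0("d", format(densities, trim = TRUE, scientific = TRUE))
  }
  if (length(schedule) == 0L || any(!is.finite(schedule)) || any(schedule < 0) ||
      any(diff(schedule) <= 0)) {
    abort("`schedule` must be non-empty, non-negative and strictly increasing.")
  }
  if (!is.numeric(replicates) || replicates < 1) abort("`replicates` must be >= 1.")
  if (!is.numeric(biological_cv) || biological_cv < 0 || biological_cv >= 1) {
    abort("`biological_cv` must be in [0, 1).")
  }
  stopifnot(length(target_colonies) == 2L, target_colonies[1] < target_colonies[2])
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` is mandatory: supply a single integer.")
  }
  if (strain == "wild-type") stopifnot(inherits(params, "kinetic_params"))
  else check_positive_scalar(rpos_rate, "rpos_rate")
  check_positive_scalar(plated_volume_ml, "plated_volume_ml")

  structure(list(densities = densities, schedule = schedule,
                 replicates = as.integer(replicates),
                 target_colonies = target_colonies,
                 biological_cv = biological_cv, strain = strain,
                 params = params, rpos_rate = rpos_rate,
                 plated_volume_ml = plated_volume_ml,
                 counting_noise = isTRUE(counting_noise),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", length(x$densities), x$strain,
      "culture(s), t =", min(x$schedule), "-", max(x$schedule), "hr,",
      x$replicates, "replicates, seed", x$seed, "\n")
  invisible(x)
}

#' Saturating density from initial glycerol
#'
#' Batch cultures arrest when the carbon source runs out, so the arrest
#' density is linear in the initial glycerol concentration. The default
#' yield, 1.4e8 cells/ml per mM, is anchored at 5 mM glycerol giving
#' ~7e8 cells/ml.
#'
#' @param conc Initial glycerol, mM. Must be >= 0; vectorized.
#' @param yield Cells/ml per mM glycerol.
#' @return Arrest density, cells/ml.
#' @export
#' @examples
#' density_from_glycerol(c(0.05, 5)) # ~7e6 and 7e8 cells/ml
density_from_glycerol <- function(conc, yield = 1.4e8) {
  check_nonnegative(conc, "conc")
  check_positive_scalar(yield, "yield")
  yield * conc
}

#' Noise-free viable density of a configured culture
#'
#' The ground truth the plate-count sampler draws around: the biphasic
#' closed form for wild-type cultures, a pure single exponential at
#' `rpos_rate` for the general-stress-response deletion strain.
#'
#' @param t Time(s), hr.
#' @param config An [experiment_config()].
#' @param density Arrest density of this culture, cells/ml.
#' @return Viable density (cells/ml) at each `t`.
#' @export
true_density <- function(t, config, density) {
  stopifnot(inherits(config, "experiment_config"))
  check_positive_scalar(density, "density")
  switch(config$strain,
         "wild-type" = cfu_closed_form(t, density, config$params),
         "delta-rpoS" = {
           check_nonnegative(t, "t")
           density * exp(-config$rpos_rate * t)
         },
         abort(paste0("unknown strain label: ", config$strain)))
}

# Pick the power-of-ten dilution whose expected plate count falls in (or
# nearest to) the target band. Returns the dilution factor (10^k, k >= 0).
select_dilution <- function(true_cfu, plated_volume_ml, band) {
  k <- 0:18
  expected <- true_cfu * plated_volume_ml / 10^k
  dist <- ifelse(expected < band[1], band[1] - expected,
                 ifelse(expected > band[2], expected - band[2], 0))
  10^k[which.min(dist)]
}

#' Simulate replicate plate counts at one (culture, time) point
#'
#' Serial-dilution spread-plate measurement: a shared lognormal biological
#' factor (CV = `biological_cv`) perturbs the true density of the culture at
#' this time; the power-of-ten dilution is chosen so the expected plate count
#' lands in (or nearest) the target band; each replicate plate then draws an
#' independent Poisson colony count at that expectation. If even undiluted
#' plating expects less than one colony, the point is recorded as zero
#' colonies with `lod = TRUE` (limit of detection).
#'
#' @param true_cfu True viable density, cells/ml. Must be > 0.
#' @param config An [experiment_config()].
#' @param seed Integer seed for this sampling call (the dataset generator
#'   derives one per (culture, time) from `config$seed`).
#' @return A tibble with one row per replicate: `replicate`,
#'   `dilution_factor`, `colonies`, `cfu_per_ml`, `lod`.
#'   `cfu_per_ml = colonies * dilution_factor / plated_volume_ml` exactly.
#' @export
#' @examples
#' cfg <- experiment_config(densities = 9e6, seed = 1)
#' sample_plate_counts(1.5e7, cfg, seed = 42)
sample_plate_counts <- function(true_cfu, config, seed) {
  stopifnot(inherits(config, "experiment_config"))
  check_positive_scalar(true_cfu, "true_cfu")
  withr::with_seed(as.integer(seed), {
    cv <- config$biological_cv
    bio <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    lam <- true_cfu * bio
    dil <- select_dilution(lam, config$plated_volume_ml, config$target_colonies)
    expected <- lam * config$plated_volume_ml / dil
    if (dil == 1 && expected < 1) {
      colonies <- rep(0, config$replicates)
      lod <- TRUE
    } else if (config$counting_noise) {
      colonies <- rpois(config$replicates, expected)
      lod <- FALSE
    } else {
      colonies <- rep(expected, config$replicates)
      lod <- FALSE
    }
    tibble(replicate = seq_len(config$replicates),
           dilution_factor = dil,
           colonies = colonies,
           cfu_per_ml = colonies * dil / config$plated_volume_ml,
           lod = lod)
  })
}

#' Generate a full synthetic plate-count experiment
#'
#' Runs every configured culture through [true_density()] and
#' [sample_plate_counts()] at each scheduled time, and averages replicate
#' `cfu_per_ml` per (culture, time) into per-culture trajectories, as plate
#' counts are reported as the mean of the replicate measurements.
#'
#' @param config An [experiment_config()].
#' @return A list of class `plate_count_experiment` with elements
#'   \describe{
#'     \item{counts}{replicate-level tibble: `strain`, `density_label`,
#'       `n0`, `time_hr`, `replicate`, `dilution_factor`, `colonies`,
#'       `cfu_per_ml`, `lod`, `seed`}
#'     \item{trajectories}{replicate-averaged tibble: `strain`,
#'       `density_label`, `n0`, `time_hr`, `cfu_per_ml`}
#'     \item{config}{the input configuration}
#'   }
#' @export
#' @examples
#' ds <- generate_dataset(experiment_config(densities = c(9e6, 7e8), seed = 7))
#' head(ds$trajectories)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$densities) == 0L) abort("`densities` must be non-empty.")

  # one independent sampling seed per (culture, time), derived reproducibly
  grid <- tidyr::expand_grid(
    density_label = names(config$densities),
    time_hr = config$schedule
  )
  sub_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max - 1L, nrow(grid)))

  counts <- purrr::pmap(
    list(grid$density_label, grid$time_hr, sub_seeds),
    function(label, t, s) {
      n0 <- config$densities[[label]]
      truth <- true_density(t, config, n0)
      rec <- sample_plate_counts(truth, config, seed = s)
      dplyr::mutate(rec,
                    strain = config$strain, density_label = label,
                    n0 = n0, time_hr = t, seed = config$seed,
                    .before = 1L)
    }
  )
  counts <- dplyr::bind_rows(counts)

  trajectories <- counts |>
    dplyr::group_by(.data$strain, .data$density_label, .data$n0, .data$time_hr) |>
    dplyr::summarise(cfu_per_ml = mean(.data$cfu_per_ml), .groups = "drop") |>
    dplyr::arrange(.data$density_label, .data$time_hr)

  structure(list(counts = counts, trajectories = trajectories, config = config),
            class = "plate_count_experiment")
}

#' @export
print.plate_count_experiment <- function(x, ...) {
  cat("<plate_count_experiment>", nrow(x$counts), "plate counts,",
      length(x$config$densities), "culture(s), seed", x$config$seed, "\n")
  invisible(x)
}
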