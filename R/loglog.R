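#' Log-log transform of a survival trajectory
#'
#' Maps a viable-density time series to coordinates that read off the
#' power-law exponent of an exponential decay: `x = log10(t)` and
#' `y = log10(ln(N0 / N))`. A pure exponential `N0 * exp(-c1 * t)` becomes
#' the line `y = x + log10(c1)` (slope 1); a Gaussian-in-time decay
#' `N0 * exp(-c2 * t^2)` becomes `y = 2 x + log10(c2)` (slope 2). The inner
#' logarithm is natural and the outer base-10; slopes are invariant to both
#' choices, intercepts follow this convention.
#'
#' Points with `t <= 0` or `N >= N0` (inner log undefined or non-positive,
#' e.g. a noisy early plateau) are dropped and counted in `n_dropped`.
#'
#' @param traj Data frame with columns `time_hr` and `cfu_per_ml` (one
#'   culture). `N0` is the value at the earliest time.
#' @param n0 Optional override for the arrest density; defaults to the value
#'   at the earliest time.
#' @return A tibble of class `loglog_series` with columns `x`, `y`,
#'   `time_hr`, and attributes `n_dropped`, `n0`, `source`.
#' @export
#' @examples
#' kp <- kinetic_params()
#' traj <- tibble::tibble(time_hr = seq(0, 288, 12),
#'                        cfu_per_ml = cfu_closed_form(seq(0, 288, 12), 9e6, kp))
#' loglog_transform(traj)
loglog_transform <- function(traj, n0 = NULL) {
  traj <- as_trajectory_frame(traj)
  if (is.null(n0)) n0 <- traj$cfu_per_ml[which.min(traj$time_hr)]
  check_positive_scalar(n0, "n0")

  keep <- traj$time_hr > 0 & traj$cfu_per_ml < n0
  dropped <- sum(!keep)
  pts <- traj[keep, , drop = FALSE]
  if (nrow(pts) < 3L) {
    abort(paste0("log-log transform retains ", nrow(pts),
                 " point(s) (", dropped, " dropped); need at least 3."))
  }
  out <- tibble(x = log10(pts$time_hr),
                y = log10(log(n0 / pts$cfu_per_ml)),
                time_hr = pts$time_hr)
  out <- out[order(out$x), ]
  structure(out,
            n_dropped = dropped, n0 = n0,
            source = attr(traj, "source", exact = TRUE) %||% NA_character_,
            class = c("loglog_series", class(tibble())))
}

# Accept any data frame carrying time_hr/cfu_per_ml; basic validation.
as_trajectory_frame <- function(traj) {
  if (!is.data.frame(traj)) abort("`traj` must be a data frame.")
  missing_cols <- setdiff(c("time_hr", "cfu_per_ml"), names(traj))
  if (length(missing_cols)) {
    abort(paste0("`traj` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(traj) < 2L) abort("`traj` must have at least 2 rows.")
  if (any(!is.finite(traj$time_hr)) || any(!is.finite(traj$cfu_per_ml))) {
    abort("`traj` contains non-finite time or density values.")
  }
  if (any(traj$cfu_per_ml < 0)) abort("`traj` densities must be non-negative.")
  traj <- traj[order(traj$time_hr), , drop = FALSE]
  if (any(duplicated(traj$time_hr))) abort("`traj` has duplicated time points; average replicates first.")
  traj
}

#' Least-squares slope of a log-log series over an index window
#'
#' Ordinary least squares of `y` on `x` restricted to the given points.
#'
#' @param series A [loglog_transform()] result (or any data frame with `x`, `y`).
#' @param window Integer indices of the points to use (>= 3).
#' @return A tibble with `slope`, `se`, `n`.
#' @export
window_slope <- function(series, window = seq_len(nrow(series))) {
  window <- as.integer(window)
  if (length(window) < 3L) abort("`window` must cover at least 3 points.")
  if (any(window < 1L | window > nrow(series))) abort("`window` out of range.")
  x <- series$x[window]
  y <- series$y[window]
  if (diff(range(x)) == 0) abort("degenerate window: all x values equal.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- if (nrow(sm) == 2L && !is.nan(sm["x", "Std. Error"])) sm["x", "Std. Error"] else 0
  tibble(slope = unname(coef(fit)[["x"]]), se = se, n = length(window))
}

# index windows for the early/late diagnostics
window_indices <- function(n, frac, side = c("early", "late")) {
  side <- match.arg(side)
  k <- max(3L, ceiling(frac * n))
  if (side == "early") seq_len(k) else seq.int(n - k + 1L, n)
}

#' Classify survival kinetics from the log-log diagnostic
#'
#' Biphasic decay shows slope ~2 early and slope ~1 late; a single
#' exponential shows slope ~1 in both windows. Windows are the first and
#' last `window_frac` of the retained points; anything else is
#' `"indeterminate"` (including first-phase-only series whose late window
#' still rides the quadratic branch).
#'
#' @param series A [loglog_transform()] result.
#' @param tol Absolute slope tolerance around 1 and 2. Default 0.3.
#' @param window_frac Fraction of points in each window. Default 0.3.
#' @return A tibble with `classification`, `early_slope`, `late_slope`,
#'   `early_se`, `late_se`.
#' @export
classify_kinetics <- function(series, tol = 0.3, window_frac = 0.3) {
  n <- nrow(series)
  early_idx <- window_indices(n, window_frac, "early")
  late_idx <- window_indices(n, window_frac, "late")
  if (length(intersect(early_idx, late_idx)) == length(union(early_idx, late_idx))) {
    abort("too few points: early and late windows coincide entirely.")
  }
  early <- window_slope(series, early_idx)
  late <- window_slope(series, late_idx)
  cls <- if (abs(early$slope - 2) <= tol && abs(late$slope - 1) <= tol) {
    "biphasic"
  } else if (abs(early$slope - 1) <= tol && abs(late$slope - 1) <= tol) {
    "single-phase"
  } else {
    "indeterminate"
  }
  tibble(classification = cls,
         early_slope = early$slope, late_slope = late$slope,
         early_se = early$se, late_se = late$se)
}

#' Breakpoint estimate from intersecting fixed-slope lines
#'
#' Fits a slope-2 line to the early subset and a slope-1 line to the late
#' subset of the log-log series (intercepts free, slopes fixed) and returns
#' the time at which they intersect, `t = c1 / c2` where `c1`, `c2` are the
#' fitted per-phase coefficients. Subsets are found by iterated assignment:
#' split at the geometric midpoint of the time span, fit both lines,
#' reassign each point to the nearer line (vertical distance, ties to the
#' early line), repeat to a fixed point (max 50 iterations).
#'
#' In the noiseless limit with an intercept-free slope-1 asymptote this
#' estimator returns `mu / (c * N0)`, i.e. twice the tangency time
#' `T0 = mu / (2 c N0)` of the model; on finite windows it sits somewhat
#' below that. The constrained model fit ([fit_piecewise_constrained()])
#' is the authoritative `T0`.
#'
#' @param series A [loglog_transform()] result, classified biphasic.
#' @return A tibble with `t0_lines` (hr), `log10_c1`, `log10_c2`,
#'   `n_early`, `n_late`, `iterations`.
#' @export
estimate_t0_lines <- function(series) {
  n <- nrow(series)
  if (n < 4L) abort("need at least 4 points to fit two lines.")
  x <- series$x
  y <- series$y

  mid_x <- mean(range(x)) # geometric midpoint of the time span
  early <- x <= mid_x
  if (sum(early) < 2L) early <- seq_len(n) <= 2L
  if (sum(!early) < 2L) early <- seq_len(n) <= (n - 2L)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    a2 <- mean(y[early] - 2 * x[early])   # log10(c2)
    a1 <- mean(y[!early] - x[!early])     # log10(c1)
    d_early <- abs(y - (2 * x + a2))
    d_late <- abs(y - (x + a1))
    new_early <- d_early <= d_late        # ties go to the early subset
    # keep both subsets fittable
    if (sum(new_early) < 2L || sum(!new_early) < 2L) break
    if (identical(new_early, early) || iter >= 50L) {
      early <- new_early
      break
    }
    early <- new_early
  }
  a2 <- mean(y[early] - 2 * x[early])
  a1 <- mean(y[!early] - x[!early])
  t0 <- 10^(a1 - a2)
  span <- range(series$time_hr)
  if (!is.finite(t0)) {
    abort(paste0("slope-1/slope-2 line fits do not intersect at a finite time; ",
                 "intercepts log10(c1) = ", format(a1), ", log10(c2) = ", format(a2)))
  }
  tibble(t0_lines = t0, log10_c1 = a1, log10_c2 = a2,
         n_early = sum(early), n_late = sum(!early), iterations = iter,
         in_span = t0 >= span[1] && t0 <= span[2])
}

#' Power-law scaling exponent across arrest densities
#'
#' OLS slope of `log10(value)` on `log10(n0)`: -1 for quantities inversely
#' proportional to density (the first-phase duration `T0`), +1 for
#' quantities linear in density (the first-phase coefficient `c2`).
#'
#' @param pairs Data frame with columns `n0` and `value`, all positive,
#'   at least 3 rows.
#' @return A tibble with `exponent`, `se`, `n`.
#' @export
#' @examples
#' scaling_exponent(tibble::tibble(n0 = c(1e6, 1e7, 1e8), value = 3 / c(1e6, 1e7, 1e8)))
scaling_exponent <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("n0", "value") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns `n0` and `value`.")
  }
  if (nrow(pairs) < 3L) abort("need at least 3 (n0, value) pairs.")
  if (any(pairs$n0 <= 0) || any(pairs$value <= 0)) {
    abort("`n0` and `value` must all be positive for log-log regression.")
  }
  fit <- lm(log10(value) ~ log10(n0), data = pairs)
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- sm[2, "Std. Error"]
  tibble(exponent = unname(coef(fit)[[2]]),
         se = if (is.nan(se)) 0 else se,
         n = nrow(pairs))
}

#' Per-culture log-log analysis of a trajectory table
#'
#' Convenience wrapper: groups a trajectory table by culture, applies
#' [loglog_transform()], [classify_kinetics()] and (for biphasic series)
#' [estimate_t0_lines()], and rolls the results into one row per culture.
#'
#' @param trajectories Tibble with columns `strain`, `density_label`, `n0`,
#'   `time_hr`, `cfu_per_ml` (the format produced by [generate_dataset()]
#'   and [read_trajectories()]).
#' @param tol,window_frac Passed to [classify_kinetics()].
#' @return A tibble, one row per culture: slopes, classification, `t0_lines`
#'   (NA when not biphasic), `t0_tangent = t0_lines / 2`, `n_dropped`.
#' @export
analyze_trajectories <- function(trajectories, tol = 0.3, window_frac = 0.3) {
  trajectories |>
    dplyr::group_by(.data$strain, .data$density_label, .data$n0) |>
    dplyr::group_modify(function(df, key) {
      series <- loglog_transform(df)
      cls <- classify_kinetics(series, tol = tol, window_frac = window_frac)
      t0 <- if (cls$classification == "biphasic") {
        tryCatch(estimate_t0_lines(series)$t0_lines, error = function(e) NA_real_)
      } else NA_real_
      dplyr::mutate(cls,
                    t0_lines = t0, t0_tangent = t0 / 2,
                    n_dropped = attr(series, "n_dropped"),
                    n_points = nrow(series))
    }) |>
    dplyr::ungroup()
}
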