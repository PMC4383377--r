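# Fitting the survival law to CFU trajectories.
#
# All objectives are least squares on ln N (multiplicative measurement error,
# matching the semi-log presentation of plate-count data). Zero or
# limit-of-detection observations are excluded and counted.

new_starve_fit <- function(method, params, stderr, t0, n1, sse_log, n_points,
                           n_excluded, classification, converged, data,
                           details = list()) {
  structure(list(method = method, params = params, stderr = stderr,
                 t0 = t0, n1 = n1, sse_log = sse_log, n_points = n_points,
                 n_excluded = n_excluded, classification = classification,
                 converged = converged, data = data, details = details),
            class = "starve_fit")
}

#' @export
print.starve_fit <- function(x, ...) {
  cat("<starve_fit>", x$method, "\n")
  for (nm in names(x$params)) {
    cat(" ", nm, "=", format(x$params[[nm]]),
        if (!is.null(x$stderr[[nm]]) && is.finite(x$stderr[[nm]]))
          paste0("(se ", format(x$stderr[[nm]], digits = 3), ")") else "", "\n")
  }
  if (!is.null(x$t0) && all(is.finite(x$t0)))
    cat("  T0 =", paste(format(x$t0, digits = 4), collapse = ", "), "hr\n")
  cat("  sse_log =", format(x$sse_log, digits = 4),
      "on", x$n_points, "points;", x$classification, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.starve_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(unlist(x$params)),
         std.error = unname(unlist(x$stderr[names(x$params)])))
}

#' @exportS3Method generics::glance
glance.starve_fit <- function(x, ...) {
  tibble(method = x$method, sse_log = x$sse_log, n_points = x$n_points,
         n_excluded = x$n_excluded, converged = x$converged,
         classification = x$classification)
}

# pull one culture's usable (t, ln N) points
fit_points <- function(traj) {
  traj <- as_trajectory_frame(traj)
  lod <- if ("lod" %in% names(traj)) traj$lod else rep(FALSE, nrow(traj))
  usable <- traj$cfu_per_ml > 0 & !lod
  list(t = traj$time_hr[usable], ln_n = log(traj$cfu_per_ml[usable]),
       n_excluded = sum(!usable))
}

#' Fit a single-exponential decay
#'
#' OLS of `ln N` on `t` with free intercept: the empirical late-phase /
#' high-density law `N ~ exp(-c1 * t)`. The rate `c1` is minus the slope.
#'
#' @param traj Data frame with columns `time_hr`, `cfu_per_ml` (one culture).
#' @return A `starve_fit` with parameter `c1` (hr^-1).
#' @export
#' @examples
#' t <- seq(0, 288, 12)
#' fit_single_exponential(tibble::tibble(time_hr = t, cfu_per_ml = 7e8 * exp(-0.018 * t)))
fit_single_exponential <- function(traj) {
  pts <- fit_points(traj)
  if (length(pts$t) < 3L) abort("single-exponential fit needs at least 3 usable points.")
  fit <- lm(pts$ln_n ~ pts$t)
  sm <- suppressWarnings(summary(fit))$coefficients
  c1 <- -unname(coef(fit)[[2]])
  se <- sm[2, "Std. Error"]
  res <- sum(fit$residuals^2)
  new_starve_fit("single-exponential",
                 params = list(c1 = c1),
                 stderr = list(c1 = if (is.nan(se)) 0 else se),
                 t0 = NA_real_, n1 = exp(unname(coef(fit)[[1]])),
                 sse_log = res, n_points = length(pts$t),
                 n_excluded = pts$n_excluded,
                 classification = "single-phase", converged = TRUE,
                 data = traj)
}

#' Fit the first (Gaussian-in-time) phase
#'
#' Through-origin OLS of `ln(N0 / N)` on `t^2` over points with
#' `t < t_max`: the empirical first-phase law `N ~ exp(-c2 * t^2)`. `N0` is
#' the value at the earliest time.
#'
#' @param traj Data frame with columns `time_hr`, `cfu_per_ml` (one culture).
#' @param t_max Upper time bound (hr) of the first-phase window, e.g. an
#'   estimate of `T0`.
#' @return A `starve_fit` with parameter `c2` (hr^-2).
#' @export
fit_first_phase <- function(traj, t_max) {
  check_positive_scalar(t_max, "t_max")
  pts <- fit_points(traj)
  n0 <- pts$ln_n[which.min(pts$t)]
  keep <- pts$t < t_max
  if (sum(keep) < 3L) abort("first-phase fit needs at least 3 usable points with t < t_max.")
  tt2 <- pts$t[keep]^2
  yy <- n0 - pts$ln_n[keep]
  fit <- lm(yy ~ tt2 + 0)
  sm <- suppressWarnings(summary(fit))$coefficients
  se <- sm[1, "Std. Error"]
  new_starve_fit("first-phase",
                 params = list(c2 = unname(coef(fit)[[1]])),
                 stderr = list(c2 = if (is.nan(se)) 0 else se),
                 t0 = NA_real_, n1 = NA_real_,
                 sse_log = sum(fit$residuals^2), n_points = sum(keep),
                 n_excluded = pts$n_excluded + sum(!keep),
                 classification = "first-phase", converged = TRUE,
                 data = traj)
}

# ln of the closed-form law, vectorized over t, parameters on natural scale
ln_model <- function(t, n0, mu, c) {
  t0 <- mu / (2 * c * n0)
  ifelse(t < t0,
         log(n0) - c * n0 * t^2,
         log(n0) + mu * t0 / 2 - mu * t)
}

# summed log-residual objective over a list of point sets, shared (mu, c)
sse_objective <- function(theta, point_sets) {
  mu <- exp(theta[1]); c <- exp(theta[2])
  s <- 0
  for (p in point_sets) {
    s <- s + sum((p$ln_n - ln_model(p$t, p$n0, mu, c))^2)
  }
  s
}

# initial values from the data: mu from the late-window ln-slope, c from the
# early-window quadratic coefficient of ln(N0/N).
init_theta <- function(point_sets, bounds) {
  mus <- vapply(point_sets, function(p) {
    n <- length(p$t)
    idx <- seq.int(max(1L, n - max(3L, ceiling(0.3 * n)) + 1L), n)
    if (length(idx) >= 2 && diff(range(p$t[idx])) > 0) {
      -unname(coef(lm(p$ln_n[idx] ~ p$t[idx]))[[2]])
    } else NA_real_
  }, numeric(1))
  cs <- vapply(point_sets, function(p) {
    idx <- which(p$t > 0)
    idx <- idx[seq_len(min(length(idx), max(3L, ceiling(0.3 * length(idx)))))]
    if (length(idx) >= 2) {
      y <- p$ln_n[which.min(p$t)] - p$ln_n[idx]
      cc <- unname(coef(lm(y ~ 0 + I(p$t[idx]^2)))[[1]]) / p$n0
      if (is.finite(cc) && cc > 0) cc else NA_real_
    } else NA_real_
  }, numeric(1))
  mu0 <- stats::median(mus, na.rm = TRUE)
  c0 <- stats::median(cs, na.rm = TRUE)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- 0.02
  if (!is.finite(c0) || c0 <= 0) c0 <- 1e-11
  c(log(clamp(mu0, bounds$mu[1], bounds$mu[2])),
    log(clamp(c0, bounds$c[1], bounds$c[2])))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# multistart bounded minimization on log-parameters
run_multistart <- function(point_sets, n_starts, fit_seed, bounds) {
  lower <- log(c(bounds$mu[1], bounds$c[1]))
  upper <- log(c(bounds$mu[2], bounds$c[2]))
  base <- init_theta(point_sets, bounds)
  perturb <- withr::with_seed(as.integer(fit_seed), {
    matrix(stats::runif(2 * n_starts, -log(10), log(10)), ncol = 2)
  })
  starts <- rbind(base, sweep(perturb, 2, base, `+`))
  starts <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                 rep(upper, each = nrow(starts)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[i, ], sse_objective, point_sets = point_sets,
                    lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("constrained fit failed: no optimizer start converged.")
  best
}

# standard errors from the numerical Hessian of the SSE at the optimum,
# on the natural (mu, c) scale: cov = sigma2 * (H/2)^-1
hessian_stderr <- function(point_sets, mu, c, sse, n_points) {
  # differentiate in units of the estimates themselves (z = p / p_hat) so the
  # finite-difference step is well-scaled for c ~ 1e-12
  f_scaled <- function(z) sse_objective(log(c(mu * z[1], c * z[2])), point_sets)
  se <- tryCatch({
    h_z <- pracma::hessian(f_scaled, c(1, 1))
    dof <- max(n_points - 2L, 1L)
    sigma2 <- sse / dof
    cov_z <- sigma2 * solve(h_z / 2)
    sqrt(pmax(diag(cov_z), 0)) * c(mu, c)
  }, error = function(e) c(NA_real_, NA_real_))
  list(mu = se[1], c = se[2])
}

#' Constrained piecewise fit of the biphasic law to one trajectory
#'
#' Least squares of `ln(model)` against `ln(data)` over the whole trajectory
#' with the full closed-form law: two free parameters `(mu, c)`, transition
#' time tied to `T0 = mu / (2 c N0)` and second-phase intercept set by
#' continuity. `N0` is anchored to the first measured value, not fitted.
#' Optimization runs on log-parameters with bounds
#' `mu in [1e-4, 1]` hr^-1, `c in [1e-16, 1e-6]` ml hr^-2, from a
#' data-driven start plus `n_starts` log-uniform perturbations (within a
#' factor of 10 either way), deterministic given `fit_seed`. Standard errors
#' come from the numerical Hessian of the objective; they are reported as
#' `NA`/infinite when the data do not constrain a direction (e.g. purely
#' single-phase data leave `c` unidentified beyond an upper bound).
#'
#' @param traj Data frame with `time_hr`, `cfu_per_ml` (one culture;
#'   optional `lod` column marks excluded limit-of-detection points).
#' @param n_starts Number of random restarts beyond the data-driven start.
#' @param fit_seed Integer seed for the restart perturbations.
#' @param bounds List with elements `mu` and `c`, each `c(lower, upper)`.
#' @return A `starve_fit` with parameters `mu`, `c`, derived `t0`, `n1`,
#'   and a phase classification from the fitted `T0` relative to the
#'   sampled window.
#' @export
#' @examples
#' kp <- kinetic_params()
#' t <- seq(0, 288, 12)
#' traj <- tibble::tibble(time_hr = t, cfu_per_ml = cfu_closed_form(t, 9e6, kp))
#' fit_piecewise_constrained(traj)
fit_piecewise_constrained <- function(traj, n_starts = 10, fit_seed = 1,
                                      bounds = list(mu = c(1e-4, 1),
                                                    c = c(1e-16, 1e-6))) {
  pts <- fit_points(traj)
  if (length(pts$t) < 5L) abort("constrained piecewise fit needs at least 5 usable points.")
  pts$n0 <- exp(pts$ln_n[which.min(pts$t)])
  point_sets <- list(pts)

  best <- run_multistart(point_sets, n_starts, fit_seed, bounds)
  mu <- exp(best$par[1]); c <- exp(best$par[2])
  t0 <- mu / (2 * c * pts$n0)
  n1 <- pts$n0 * exp(-c * pts$n0 * t0^2 + mu * t0)
  se <- hessian_stderr(point_sets, mu, c, best$objective, length(pts$t))

  pos_t <- pts$t[pts$t > 0]
  cls <- if (t0 <= min(pos_t)) "single-phase"
         else if (t0 >= max(pts$t)) "first-phase"
         else "biphasic"
  new_starve_fit("piecewise-constrained",
                 params = list(mu = mu, c = c),
                 stderr = se, t0 = t0, n1 = n1,
                 sse_log = best$objective, n_points = length(pts$t),
                 n_excluded = pts$n_excluded, classification = cls,
                 converged = best$convergence == 0, data = traj,
                 details = list(n0 = pts$n0, optimizer = best$message))
}

#' Global constrained fit across densities
#'
#' The authoritative estimator: one shared `(mu, c)` minimizing the summed
#' log-residual objective over all cultures, each with its own anchored
#' `N0` and derived `T0 = mu / (2 c N0)`. Because the law depends on the
#' density only through `c * N0`, a single-density dataset leaves the
#' `(k * N0, c / k)` direction degenerate; multiple distinct densities pin
#' the scaling down.
#'
#' @param trajectories Tibble with columns `density_label`, `time_hr`,
#'   `cfu_per_ml` (and optionally `strain`, `n0`, `lod`) covering two or
#'   more cultures, as produced by [generate_dataset()] or
#'   [read_trajectories()].
#' @inheritParams fit_piecewise_constrained
#' @return A `starve_fit` with shared `mu`, `c`; `t0` and `n1` are named
#'   vectors, one element per culture.
#' @export
#' @examples
#' ds <- generate_dataset(experiment_config(densities = c(9e6, 5e7, 7e8), seed = 3))
#' fit <- fit_global(ds$trajectories)
#' tidy(fit)
fit_global <- function(trajectories, n_starts = 10, fit_seed = 1,
                       bounds = list(mu = c(1e-4, 1), c = c(1e-16, 1e-6))) {
  if (!is.data.frame(trajectories) || !"density_label" %in% names(trajectories)) {
    abort("`trajectories` must be a data frame with a `density_label` column.")
  }
  groups <- split(trajectories, trajectories$density_label)
  point_sets <- purrr::map(groups, function(g) {
    p <- fit_points(g)
    p$n0 <- exp(p$ln_n[which.min(p$t)])
    p
  })
  point_sets <- point_sets[vapply(point_sets, function(p) length(p$t) >= 3L, logical(1))]
  if (length(point_sets) < 1L) abort("no culture has enough usable points.")
  n0s <- vapply(point_sets, `[[`, numeric(1), "n0")
  if (length(point_sets) < 2L) {
    warn("fit_global called with a single culture: mu and c are identifiable only up to the c*N0 product's scaling; supply multiple densities.")
  } else if (length(unique(signif(n0s, 6))) == 1L) {
    warn("all cultures share the same density; the density scaling of c is untested.")
  }

  best <- run_multistart(point_sets, n_starts, fit_seed, bounds)
  mu <- exp(best$par[1]); c <- exp(best$par[2])
  t0 <- mu / (2 * c * n0s)
  n1 <- n0s * exp(-c * n0s * t0^2 + mu * t0)
  n_tot <- sum(vapply(point_sets, function(p) length(p$t), integer(1)))
  se <- hessian_stderr(point_sets, mu, c, best$objective, n_tot)

  new_starve_fit("global-constrained",
                 params = list(mu = mu, c = c),
                 stderr = se, t0 = t0, n1 = n1,
                 sse_log = best$objective, n_points = n_tot,
                 n_excluded = sum(vapply(point_sets, `[[`, integer(1), "n_excluded")),
                 classification = "global", converged = best$convergence == 0,
                 data = trajectories,
                 details = list(n0 = n0s, optimizer = best$message))
}

#' Fitted densities from a starve_fit
#'
#' @param object A `starve_fit` from [fit_piecewise_constrained()] or
#'   [fit_global()].
#' @param t Times (hr) at which to evaluate the fitted law.
#' @param n0 Arrest density; defaults to the fit's anchored value (required
#'   explicitly for global fits, which carry several).
#' @param ... Unused.
#' @return Tibble with `time_hr` and fitted `cfu_per_ml`.
#' @export
predict_cfu <- function(object, t, n0 = NULL, ...) {
  stopifnot(inherits(object, "starve_fit"))
  if (!object$method %in% c("piecewise-constrained", "global-constrained")) {
    abort("predict_cfu() supports constrained fits only.")
  }
  if (is.null(n0)) {
    n0s <- object$details$n0
    if (length(n0s) != 1L) abort("supply `n0`: this global fit covers several densities.")
    n0 <- n0s
  }
  tibble(time_hr = t,
         cfu_per_ml = exp(ln_model(t, n0, object$params$mu, object$params$c)))
}
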