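#' Net population rate as a function of residual substrate
#'
#' The linearized rate law of the maintenance model:
#' `lambda(S) = mu * (S / s1 - 1)` for `0 <= S <= s1`, i.e. zero at the
#' arrest concentration `S = s1` and `-mu` at `S = 0`. For `S > s1` the same
#' line is extrapolated; the starvation pipeline never enters that region
#' (time zero is defined at growth arrest, where `S = s1`), so values there
#' are for plotting only.
#'
#' @param s Substrate concentration(s), uM. Must be >= 0; vectorized.
#' @param mech A [mechanistic_params()] object.
#' @return Net rate(s), hr^-1. Negative below `s1`, zero at `s1`.
#' @seealso [lambda_monod()] for the saturating contrast model, which can
#'   never be negative and therefore cannot describe death.
#' @export
#' @examples
#' mp <- mechanistic_params(mu = 0.018, s1 = 1, m = 5.2e-10)
#' lambda_substrate(c(0, 0.5, 1), mp) # -mu, -mu/2, 0
lambda_substrate <- function(s, mech) {
  stopifnot(inherits(mech, "mechanistic_params"))
  check_nonnegative(s, "s")
  mech$mu * (s / mech$s1 - 1)
}

#' Monod growth rate (contrast model)
#'
#' `lambda = lambda_max * S / (ks + S)`: non-negative everywhere and zero at
#' `S = 0`. Because it cannot go negative it cannot describe population
#' decline under starvation — the structural contrast with
#' [lambda_substrate()], whose value at `S = 0` is `-mu`.
#'
#' @param s Substrate concentration(s), uM. Must be >= 0; vectorized.
#' @param lambda_max Maximal growth rate, hr^-1. Must be > 0.
#' @param ks Half-saturation concentration, uM. Must be > 0.
#' @return Growth rate(s), hr^-1, in `[0, lambda_max)`.
#' @export
#' @examples
#' lambda_monod(c(0, 2, 1e6), lambda_max = 1, ks = 2) # 0, 0.5, ~1
lambda_monod <- function(s, lambda_max, ks) {
  check_nonnegative(s, "s")
  check_positive_scalar(lambda_max, "lambda_max")
  check_positive_scalar(ks, "ks")
  lambda_max * s / (ks + s)
}

#' First-phase duration (phase-transition time)
#'
#' `T0 = mu / (2 * c * n0)`: the tangency point where the Gaussian-in-time
#' first branch and the exponential second branch of the survival law meet
#' with equal value and equal log-slope. Inversely proportional to the
#' arrest density, so doubling `n0` exactly halves `T0`.
#'
#' @param n0 Arrest density (density at growth arrest), cells/ml. Must be > 0;
#'   vectorized.
#' @param params A [kinetic_params()] object.
#' @return Transition time(s), hr.
#' @export
#' @examples
#' transition_time(9e6, kinetic_params()) # ~213 hr
#' transition_time(7e8, kinetic_params()) # ~2.7 hr: before the first sample
transition_time <- function(n0, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(n0) || any(!is.finite(n0)) || any(n0 <= 0)) {
    abort(paste0("`n0` must be positive and finite; offending value(s): ",
                 paste(format(head(n0[!is.finite(n0) | n0 <= 0], 3L)), collapse = ", ")))
  }
  params$mu / (2 * params$c * n0)
}

#' Continuity intercept of the second phase
#'
#' The prefactor `N1 = n0 * exp(-c * n0 * T0^2 + mu * T0)` that makes the
#' two branches of [cfu_closed_form()] continuous at `T0`. Since
#' `c * n0 * T0^2 = mu * T0 / 2`, this simplifies to
#' `n0 * exp(mu * T0 / 2)`, slightly above `n0`: the back-extrapolated
#' second-phase line passes above the time-zero density.
#'
#' @inheritParams transition_time
#' @return `N1`, cells/ml.
#' @export
continuity_intercept <- function(n0, params) {
  t0 <- transition_time(n0, params)
  n0 * exp(-params$c * n0 * t0^2 + params$mu * t0)
}

#' Closed-form biphasic survival law
#'
#' Viable density after growth arrest:
#' `N(t) = n0 * exp(-c * n0 * t^2)` for `t < T0` and
#' `N(t) = N1 * exp(-mu * t)` for `t >= T0`, with `T0 = mu / (2 c n0)` and
#' `N1` set by continuity ([continuity_intercept()]). The two branches are
#' tangent at `T0`: the curve is continuously differentiable and strictly
#' decreasing for `t > 0`. At arrest densities above ~1e8 cells/ml, `T0`
#' falls before the first practical sampling time and only the exponential
#' phase is observed.
#'
#' @param t Time(s) since growth arrest, hr. Must be >= 0; vectorized.
#' @inheritParams transition_time
#' @param n0 Arrest density, cells/ml (single value).
#' @return Viable density (cells/ml) at each `t`.
#' @export
#' @examples
#' kp <- kinetic_params()
#' cfu_closed_form(c(0, 48, 96, 192, 288), 9e6, kp)
cfu_closed_form <- function(t, n0, params) {
  stopifnot(inherits(params, "kinetic_params"))
  check_positive_scalar(n0, "n0")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    abort(paste0("`t` must be non-negative and finite; offending value(s): ",
                 paste(format(head(t[!is.finite(t) | t < 0], 3L)), collapse = ", ")))
  }
  t0 <- transition_time(n0, params)
  n1 <- continuity_intercept(n0, params)
  # t = T0 belongs to the second branch; the branches agree there anyway
  ifelse(t < t0,
         n0 * exp(-params$c * n0 * t^2),
         n1 * exp(-params$mu * t))
}

#' Simulate the substrate-maintenance ODE model
#'
#' Integrates `d ln N / dt = lambda(S)` with [lambda_substrate()] and a
#' maintenance drawdown of the residual substrate pool, from `S(0) = s1`
#' and `N(0) = n0`. In `"initial-density"` mode (default) the total
#' consumption rate is fixed at the arrest density, `dS/dt = -m * n0`, which
#' reproduces the closed-form law exactly: `S` hits zero at
#' `t = s1 / (m * n0) = T0` and the decay switches from Gaussian-in-time to
#' exponential. In `"current-density"` mode `dS/dt = -m * N(t)`, provided
#' for sensitivity analysis. `S` is floored at zero.
#'
#' Integration uses classical fixed-step 4th-order Runge-Kutta on `ln N`
#' (exact for the piecewise-linear rate of the default mode); the step is
#' `min(0.1, T0 / 200)` hr and the substrate-exhaustion time is inserted
#' into the step grid so no step straddles the kink.
#'
#' @param n0 Arrest density, cells/ml.
#' @param mech A [mechanistic_params()] object.
#' @param t_grid Output times, hr: starting at 0, strictly increasing.
#' @param consumption_mode `"initial-density"` or `"current-density"`.
#' @return A tibble with columns `time_hr`, `cfu_per_ml`, `substrate_uM`.
#' @export
#' @examples
#' mp <- mechanistic_from_kinetic(kinetic_params())
#' sim <- simulate_starvation_ode(9e6, mp, seq(0, 288, by = 12))
#' max(abs(sim$cfu_per_ml / cfu_closed_form(sim$time_hr, 9e6, kinetic_params()) - 1))
simulate_starvation_ode <- function(n0, mech, t_grid,
                                    consumption_mode = c("initial-density",
                                                         "current-density")) {
  stopifnot(inherits(mech, "mechanistic_params"))
  check_positive_scalar(n0, "n0")
  consumption_mode <- match.arg(consumption_mode)
  if (length(t_grid) < 1L || !is.numeric(t_grid) || any(!is.finite(t_grid)) ||
      t_grid[1] != 0 || (length(t_grid) > 1L && any(diff(t_grid) <= 0))) {
    abort("`t_grid` must be a finite numeric vector starting at 0 and strictly increasing.")
  }

  t_exhaust <- mech$s1 / (mech$m * n0)      # = T0 in initial-density mode
  step <- min(0.1, t_exhaust / 200)
  t_max <- max(t_grid)
  times <- sort(unique(c(seq(0, t_max, by = step), t_max, t_grid,
                         if (t_exhaust < t_max) t_exhaust)))

  deriv <- function(t, y, parms) {
    s <- max(y[["S"]], 0)
    dlnN <- lambda_substrate(s, mech)
    n_ref <- if (consumption_mode == "initial-density") n0 else exp(y[["lnN"]])
    dS <- if (y[["S"]] <= 0) 0 else -mech$m * n_ref
    list(c(lnN = dlnN, S = dS))
  }

  out <- deSolve::ode(y = c(lnN = log(n0), S = mech$s1), times = times,
                      func = deriv, parms = NULL, method = "rk4")
  out <- as.data.frame(out)
  keep <- match(t_grid, out$time)
  tibble(time_hr = t_grid,
         cfu_per_ml = exp(out$lnN[keep]),
         substrate_uM = pmax(out$S[keep], 0))
}
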