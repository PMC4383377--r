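#' Kinetic parameters of the biphasic survival law
#'
#' The closed-form survival law has two parameters: `mu`, the death rate once
#' the residual substrate is exhausted (hr^-1, the late-phase ln-slope), and
#' `c`, the curvature coefficient of the first phase (ml * hr^-2), which
#' multiplies the arrest density so that the first phase decays as
#' `exp(-c * N0 * t^2)`. The values fitted to glycerol-starved wild-type
#' *E. coli* are `mu = 0.018` and `c = 4.7e-12`, which are the defaults.
#'
#' @param mu Death rate at zero substrate, hr^-1. Must be > 0.
#' @param c First-phase curvature coefficient, ml * hr^-2. Must be > 0.
#'
#' @return An object of class `kinetic_params`: a named list with elements
#'   `mu` and `c`.
#' @seealso [mechanistic_params()] for the substrate-level parameterization,
#'   [cfu_closed_form()] for the survival law itself.
#' @export
#' @examples
#' kp <- kinetic_params()
#' transition_time(9e6, kp) # first-phase duration at 9e6 cells/ml, ~213 hr
kinetic_params <- function(mu = 0.018, c = 4.7e-12) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(c, "c")
  structure(list(mu = mu, c = c), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>  mu =", format(x$mu), "hr^-1,  c =",
      format(x$c), "ml*hr^-2\n")
  invisible(x)
}

#' Mechanistic (substrate-level) model parameters
#'
#' Parameterizes the maintenance-consumption model that generates the biphasic
#' law: the net population rate is linear in residual substrate,
#' `lambda(S) = mu * (S / s1 - 1)`, zero at the arrest concentration `s1` and
#' `-mu` when the substrate is gone; each cell consumes substrate for
#' maintenance at rate `m`, so the pool drains linearly. The identifiable
#' combination is `c = mu * m / (2 * s1)`; CFU data alone cannot split `c`
#' into `m` and `s1`, so fitting works on [kinetic_params()] and this object
#' is for simulation. `s1` defaults to 1 uM (residual glycerol at arrest was
#' measured in the 0.5-2 uM range) and `m` is back-solved from `c` by
#' [mechanistic_from_kinetic()].
#'
#' @param mu Death rate at zero substrate, hr^-1.
#' @param s1 Residual substrate concentration at growth arrest, uM. Must be > 0.
#' @param m Per-cell maintenance consumption rate, uM * ml / (cell * hr).
#' @param lambda_max Optional maximal Monod growth rate, hr^-1 (contrast
#'   model only; see [lambda_monod()]).
#' @param ks Optional Monod half-saturation concentration, uM.
#'
#' @return An object of class `mechanistic_params`.
#' @export
#' @examples
#' mp <- mechanistic_from_kinetic(kinetic_params())
#' derived_c(mp) # recovers c = 4.7e-12
mechanistic_params <- function(mu, s1, m, lambda_max = NULL, ks = NULL) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(s1, "s1")
  # m = 0 is the no-consumption limit: substrate stays at s1, N stays at n0
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
    abort("`m` must be a single non-negative finite number.")
  }
  if (!is.null(lambda_max)) check_positive_scalar(lambda_max, "lambda_max")
  if (!is.null(ks)) check_positive_scalar(ks, "ks")
  structure(list(mu = mu, s1 = s1, m = m,
                 lambda_max = lambda_max, ks = ks),
            class = "mechanistic_params")
}

#' @export
print.mechanistic_params <- function(x, ...) {
  cat("<mechanistic_params>  mu =", format(x$mu), "hr^-1,  s1 =",
      format(x$s1), "uM,  m =", format(x$m),
      "uM*ml/cell/hr  (c =", format(derived_c(x)), ")\n")
  invisible(x)
}

#' Curvature coefficient implied by mechanistic parameters
#'
#' @param mech A [mechanistic_params()] object.
#' @return `mu * m / (2 * s1)`, in ml * hr^-2.
#' @export
derived_c <- function(mech) {
  stopifnot(inherits(mech, "mechanistic_params"))
  mech$mu * mech$m / (2 * mech$s1)
}

#' Back-solve mechanistic parameters from kinetic ones
#'
#' Chooses the maintenance rate `m = 2 * s1 * c / mu` so the mechanistic model
#' reproduces the given kinetic parameters exactly for any `s1` (the split of
#' `c` into `m` and `s1` is not identifiable from CFU data).
#'
#' @param params A [kinetic_params()] object.
#' @param s1 Residual substrate at arrest, uM (default 1).
#' @inheritParams mechanistic_params
#' @return A [mechanistic_params()] object with `derived_c()` equal to
#'   `params$c`.
#' @export
mechanistic_from_kinetic <- function(params, s1 = 1, lambda_max = NULL, ks = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  mechanistic_params(mu = params$mu, s1 = s1,
                     m = 2 * s1 * params$c / params$mu,
                     lambda_max = lambda_max, ks = ks)
}

# shared argument checks ----------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive finite number, got ",
                 deparse(substitute(x)), " = ", paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    bad <- x[!is.finite(x) | x < 0]
    abort(paste0("`", name, "` must be non-negative and finite; offending value(s): ",
                 paste(format(head(bad, 3L)), collapse = ", ")))
  }
  invisible(x)
}
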