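# Shared fixtures: the fitted wild-type parameters of the glycerol-starvation
# study and small trajectory builders used across test files.

wt_params <- function() kinetic_params(mu = 0.018, c = 4.7e-12)

# noiseless closed-form trajectory at the default 12-h / 288-h schedule
model_trajectory <- function(n0, params = wt_params(),
                             times = seq(0, 288, by = 12)) {
  tibble::tibble(time_hr = times,
                 cfu_per_ml = cfu_closed_form(times, n0, params))
}

# pure single-exponential trajectory (the high-density / second-phase law)
exp_trajectory <- function(n0, rate, times = seq(0, 288, by = 12)) {
  tibble::tibble(time_hr = times, cfu_per_ml = n0 * exp(-rate * times))
}

# pure Gaussian-in-time trajectory (the first-phase law)
gauss_trajectory <- function(n0, c2, times = seq(0, 288, by = 12)) {
  tibble::tibble(time_hr = times, cfu_per_ml = n0 * exp(-c2 * times^2))
}

# tag a bare trajectory with the grouping columns the table-level API expects
as_culture <- function(traj, label, n0, strain = "wild-type") {
  dplyr::mutate(traj, strain = strain, density_label = label, n0 = n0,
                .before = 1)
}
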