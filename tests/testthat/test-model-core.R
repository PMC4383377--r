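test_that("substrate-linear rate law hits its anchor points and rejects bad input", {
  mp <- mechanistic_params(mu = 0.018, s1 = 1, m = 5.2e-10)
  expect_equal(lambda_substrate(mp$s1, mp), 0)
  expect_equal(lambda_substrate(0, mp), -mp$mu)
  expect_equal(lambda_substrate(mp$s1 / 2, mp), -mp$mu / 2)
  # extrapolation above s1 stays on the same line
  expect_equal(lambda_substrate(2 * mp$s1, mp), mp$mu)
  expect_error(lambda_substrate(-0.1, mp), "-0.1")
})

test_that("Monod rate is saturating, non-negative, and zero only at zero substrate", {
  expect_equal(lambda_monod(0, 1, 2), 0)
  expect_equal(lambda_monod(2, 1, 2), 0.5) # half-saturation
  expect_lt(lambda_monod(1e9, 1, 2), 1)
  expect_gt(lambda_monod(1e9, 1, 2), 0.999)
  expect_error(lambda_monod(-1, 1, 2), "non-negative")
})

test_that("Monod can never be negative while the linear law is negative below s1", {
  # the structural reason the saturating form cannot describe starvation death
  mp <- mechanistic_params(mu = 0.018, s1 = 1, m = 5.2e-10)
  s_grid <- seq(0, 5, by = 0.05)
  expect_true(all(lambda_monod(s_grid, 0.5, 0.3) >= 0))
  expect_lt(lambda_substrate(0, mp), 0)
  expect_true(all(lambda_substrate(s_grid[s_grid < mp$s1], mp) < 0))
})

test_that("transition time is inversely proportional to arrest density", {
  kp <- wt_params()
  n0 <- 9e6
  expect_equal(transition_time(2 * n0, kp), transition_time(n0, kp) / 2)

  # independent oracle: the time where the phase-1 log-slope reaches -mu,
  # found by root-finding rather than the closed formula
  oracle_t0 <- uniroot(function(t) -2 * kp$c * n0 * t + kp$mu,
                       interval = c(1e-6, 1e6), tol = 1e-10)$root
  expect_equal(transition_time(n0, kp), oracle_t0, tolerance = 1e-8)
  expect_equal(transition_time(n0, kp), 212.766, tolerance = 1e-4)

  # 1/n0 divergence at low density
  expect_gt(transition_time(1e-6, kp), 1e12)
  expect_error(transition_time(0, kp), "positive")
  expect_error(transition_time(-5, kp), "positive")
})

test_that("T0 * N0 is constant across densities for fixed parameters", {
  kp <- wt_params()
  n0s <- 10^seq(5, 9, length.out = 41)
  prods <- transition_time(n0s, kp) * n0s
  expect_lt(diff(range(prods)) / prods[1], 1e-12)
  expect_equal(prods[1], kp$mu / (2 * kp$c), tolerance = 1e-12)
})

test_that("closed-form law starts at n0, is continuous and tangent at T0", {
  kp <- wt_params()
  expect_identical(cfu_closed_form(0, 9e6, kp), 9e6)

  set.seed(421)
  for (i in seq_len(1000)) {
    kp_i <- kinetic_params(mu = 10^runif(1, -3, -1), c = 10^runif(1, -13, -10))
    n0_i <- 10^runif(1, 5, 9)
    t0 <- transition_time(n0_i, kp_i)
    # skip draws whose first phase spans so many ln-units that exp()
    # under/overflows in double precision
    if (kp_i$mu * t0 > 600) next
    n1 <- continuity_intercept(n0_i, kp_i)
    # value continuity: left branch vs right branch at T0
    left <- n0_i * exp(-kp_i$c * n0_i * t0^2)
    right <- n1 * exp(-kp_i$mu * t0)
    expect_lt(abs(left / right - 1), 1e-10)
    # log-derivative continuity: -2 c n0 T0 vs -mu
    expect_lt(abs(-2 * kp_i$c * n0_i * t0 / -kp_i$mu - 1), 1e-10)
  }
})

test_that("closed-form decay is strictly decreasing and density-accelerated in phase 1", {
  kp <- wt_params()
  t <- seq(0, 400, by = 4)
  n <- cfu_closed_form(t, 9e6, kp)
  expect_true(all(diff(n) < 0))
  # larger n0 decays by a larger relative factor at equal phase-1 time
  t_probe <- 50
  frac_low <- cfu_closed_form(t_probe, 1e6, kp) / 1e6
  frac_high <- cfu_closed_form(t_probe, 1e7, kp) / 1e7
  expect_lt(frac_high, frac_low)
  expect_error(cfu_closed_form(-1, 9e6, kp), "non-negative")
})

test_that("second-phase log-slope equals -mu exactly", {
  kp <- wt_params()
  n0 <- 9e6
  t0 <- transition_time(n0, kp)
  t <- seq(t0 + 10, t0 + 100, by = 10)
  ln_n <- log(cfu_closed_form(t, n0, kp))
  slopes <- diff(ln_n) / diff(t)
  expect_equal(slopes, rep(-0.018, length(slopes)), tolerance = 1e-12)
})

test_that("ODE simulation reproduces the closed form in initial-density mode", {
  kp <- wt_params()
  mp <- mechanistic_from_kinetic(kp)
  expect_equal(derived_c(mp), kp$c, tolerance = 1e-15)

  for (n0 in c(9e6, 1e8)) {
    t0 <- transition_time(n0, kp)
    t_grid <- seq(0, 2 * t0, length.out = 49)
    t_grid <- t_grid - t_grid[1]
    sim <- simulate_starvation_ode(n0, mp, t_grid)
    expect_equal(sim$cfu_per_ml[1], n0)
    rel <- abs(sim$cfu_per_ml / cfu_closed_form(t_grid, n0, kp) - 1)
    expect_lt(max(rel), 1e-3)
    # substrate drains linearly to zero at T0 = s1 / (m n0)
    expect_true(all(diff(sim$substrate_uM) <= 1e-12))
    after <- sim$time_hr > t0 + 0.1
    expect_true(all(sim$substrate_uM[after] == 0))
  }
})

test_that("ODE substrate exhaustion time matches the linear drawdown prediction", {
  mp <- mechanistic_params(mu = 0.02, s1 = 1, m = 4e-10)
  n0 <- 5e6
  t_exhaust <- mp$s1 / (mp$m * n0) # 500 hr
  step <- min(0.1, t_exhaust / 200)
  t_grid <- seq(0, 2 * t_exhaust, length.out = 101)
  sim <- simulate_starvation_ode(n0, mp, t_grid)
  first_zero <- min(sim$time_hr[sim$substrate_uM == 0])
  expect_lte(abs(first_zero - t_exhaust), max(step, diff(t_grid)[1]))
})

test_that("zero maintenance consumption freezes the population at n0", {
  mp <- mechanistic_params(mu = 0.018, s1 = 1, m = 0)
  sim <- simulate_starvation_ode(3e7, mp, seq(0, 100, by = 10))
  expect_equal(sim$cfu_per_ml, rep(3e7, 11), tolerance = 1e-12)
  expect_equal(sim$substrate_uM, rep(1, 11))
})

test_that("current-density consumption mode slows the drawdown as cells die", {
  kp <- wt_params()
  mp <- mechanistic_from_kinetic(kp)
  n0 <- 9e6
  t_grid <- seq(0, 400, by = 10)
  sim_init <- simulate_starvation_ode(n0, mp, t_grid, "initial-density")
  sim_curr <- simulate_starvation_ode(n0, mp, t_grid, "current-density")
  expect_true(all(diff(sim_curr$substrate_uM) <= 1e-12))
  # N(t) <= N0 throughout, so current-density consumption is never faster
  expect_true(all(sim_curr$substrate_uM >= sim_init$substrate_uM - 1e-9))
})

test_that("ODE rejects malformed time grids", {
  mp <- mechanistic_params(mu = 0.018, s1 = 1, m = 5e-10)
  expect_error(simulate_starvation_ode(1e7, mp, numeric(0)), "t_grid")
  expect_error(simulate_starvation_ode(1e7, mp, c(5, 10)), "t_grid")
  expect_error(simulate_starvation_ode(1e7, mp, c(0, 10, 10)), "t_grid")
})

test_that("mechanistic and kinetic parameterizations agree through derived_c", {
  kp <- kinetic_params(mu = 0.031, c = 2.2e-12)
  mp <- mechanistic_from_kinetic(kp, s1 = 1.7)
  expect_equal(derived_c(mp), kp$c, tolerance = 1e-14)
  expect_gt(derived_c(mp), 0)
})
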