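test_that("glycerol-to-density conversion is linear through the 5 mM anchor", {
  expect_equal(density_from_glycerol(5), 7e8)
  expect_equal(density_from_glycerol(0), 0)
  expect_equal(density_from_glycerol(2.5), 3.5e8)
  expect_error(density_from_glycerol(-1), "non-negative")
})

test_that("true density follows the biphasic law for wild type and a single exponential for the rpoS deletion", {
  cfg_wt <- experiment_config(densities = 9e6, seed = 1)
  expect_equal(true_density(0, cfg_wt, 9e6), 9e6)
  tt <- seq(0, 288, by = 12)
  expect_equal(true_density(tt, cfg_wt, 9e6),
               cfu_closed_form(tt, 9e6, wt_params()))

  cfg_mut <- experiment_config(densities = 9e6, strain = "delta-rpoS", seed = 1)
  nn <- true_density(tt, cfg_mut, 9e6)
  ln_slopes <- diff(log(nn)) / diff(tt)
  expect_equal(ln_slopes, rep(-0.035, length(ln_slopes)), tolerance = 1e-12)

  # wild type at high density: late decay ratio approaches exp(-0.018 * dt)
  cfg_hi <- experiment_config(densities = 7e8, seed = 1)
  t0 <- transition_time(7e8, wt_params())
  ratio <- true_density(t0 + 60, cfg_hi, 7e8) / true_density(t0 + 48, cfg_hi, 7e8)
  expect_equal(ratio, exp(-0.018 * 12), tolerance = 1e-12)
})

test_that("dilution selection targets the 100-200 colony band", {
  # 1.5e7 cells/ml, 0.1 ml plated: only a 10^4-fold dilution gives an
  # in-band expectation (150); enumerating all powers of ten confirms it
  cfg <- experiment_config(densities = 1.5e7, biological_cv = 0,
                           counting_noise = FALSE, seed = 1)
  rec <- sample_plate_counts(1.5e7, cfg, seed = 5)
  oracle <- 10^(0:18)
  expected <- 1.5e7 * 0.1 / oracle
  in_band <- oracle[expected >= 100 & expected <= 200]
  expect_length(in_band, 1L)
  expect_equal(unique(rec$dilution_factor), in_band)
  expect_equal(unique(rec$colonies), 150)
})

test_that("expected plate count stays within practical bounds across magnitudes", {
  set.seed(99)
  true_vals <- 10^runif(200, 4, 10)
  for (v in true_vals) {
    cfg <- experiment_config(densities = v, biological_cv = 0,
                             counting_noise = FALSE, replicates = 1L, seed = 1)
    rec <- sample_plate_counts(v, cfg, seed = 2)
    expect_gte(rec$colonies, 10)
    expect_lte(rec$colonies, 2000)
  }
})

test_that("plate-count records are internally consistent and seed-reproducible", {
  cfg <- experiment_config(densities = 2e7, seed = 7)
  a <- sample_plate_counts(2e7, cfg, seed = 123)
  b <- sample_plate_counts(2e7, cfg, seed = 123)
  expect_identical(a, b)
  expect_equal(a$cfu_per_ml, a$colonies * a$dilution_factor / 0.1)

  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$trajectories, ds2$trajectories)
})

test_that("plate-count sampling is unbiased for the true density", {
  true_cfu <- 3.7e6
  cfg <- experiment_config(densities = true_cfu, replicates = 200L, seed = 1)
  # 50 independent culture-time draws x 200 replicate plates = 10^4 counts
  vals <- unlist(lapply(1:50, function(s) {
    sample_plate_counts(true_cfu, cfg, seed = 1000 + s)$cfu_per_ml
  }))
  mc_se <- sd(vals) / sqrt(length(vals))
  # the biological factor is shared within a call, so the effective spread
  # is dominated by 50 lognormal draws; widen the bound accordingly
  bio_se <- true_cfu * cfg$biological_cv / sqrt(50)
  expect_lt(abs(mean(vals) - true_cfu), 3 * (mc_se + bio_se))
})

test_that("below one countable colony the record flags the detection limit", {
  cfg <- experiment_config(densities = 5, biological_cv = 0, seed = 1)
  rec <- sample_plate_counts(5, cfg, seed = 3)
  expect_true(all(rec$lod))
  expect_true(all(rec$colonies == 0))
  expect_true(all(rec$cfu_per_ml == 0))
})

test_that("noise-free generation passes through the model exactly", {
  cfg <- experiment_config(densities = c(9e6, 7e8), biological_cv = 0,
                           counting_noise = FALSE, seed = 1)
  ds <- generate_dataset(cfg)
  truth <- purrr::map2_dbl(ds$trajectories$n0, ds$trajectories$time_hr,
                           function(n0, t) cfu_closed_form(t, n0, wt_params()))
  expect_equal(ds$trajectories$cfu_per_ml, truth, tolerance = 1e-12)
})

test_that("replicate averaging converges to the true density as replicates grow", {
  true_cfu <- 4.2e7
  cfg <- experiment_config(densities = true_cfu, biological_cv = 0,
                           replicates = 10000L, seed = 1)
  rec <- sample_plate_counts(true_cfu, cfg, seed = 11)
  # Poisson at ~150 colonies: relative SE of the mean ~ (150 * 1e4)^(-1/2)
  expect_lt(abs(mean(rec$cfu_per_ml) / true_cfu - 1), 3 / sqrt(150 * 1e4))
})

test_that("averaged replicate noise matches counting statistics in quadrature", {
  # at ~150 colonies and 3 replicates the counting part of the relative SD
  # of the averaged value is ~(150*3)^(-1/2) ~ 4.7%; with a 10% biological
  # CV the total is sqrt(0.047^2 + 0.1^2) ~ 11%
  true_cfu <- 1.5e7
  cfg <- experiment_config(densities = true_cfu, seed = 1)
  means <- vapply(1:400, function(s) {
    mean(sample_plate_counts(true_cfu, cfg, seed = 20000 + s)$cfu_per_ml)
  }, numeric(1))
  rel_sd <- sd(means) / true_cfu
  predicted <- sqrt(1 / (150 * 3) + cfg$biological_cv^2)
  expect_lt(abs(rel_sd / predicted - 1), 0.25)
})

test_that("dataset assembly respects configuration counts and decay ordering", {
  cfg1 <- experiment_config(densities = 3e6, schedule = 24, replicates = 3L, seed = 2)
  ds1 <- generate_dataset(cfg1)
  expect_equal(nrow(ds1$counts), 3L)
  expect_equal(nrow(ds1$trajectories), 1L)

  # low-density cultures lose a smaller fraction over the first 100 hr
  cfg2 <- experiment_config(densities = c(low = 5e5, high = 7e8),
                            schedule = seq(0, 96, by = 12),
                            biological_cv = 0, counting_noise = FALSE, seed = 3)
  tr <- generate_dataset(cfg2)$trajectories
  drop_frac <- tr |>
    dplyr::group_by(.data$density_label) |>
    dplyr::summarise(frac = .data$cfu_per_ml[dplyr::n()] / .data$cfu_per_ml[1])
  expect_gt(drop_frac$frac[drop_frac$density_label == "low"],
            drop_frac$frac[drop_frac$density_label == "high"])
})

test_that("experiment configuration validates its inputs", {
  expect_error(experiment_config(seed = 1), "densities")
  expect_error(experiment_config(densities = numeric(0), seed = 1), "non-empty")
  expect_error(experiment_config(densities = 1e6), "seed")
  expect_error(experiment_config(densities = 1e6, biological_cv = 1.2, seed = 1),
               "biological_cv")
  expect_error(experiment_config(densities = 1e6, schedule = c(10, 5), seed = 1),
               "schedule")
  cfg <- experiment_config(glycerol_mM = c(0.05, 5), seed = 1)
  expect_equal(unname(cfg$densities), c(7e6, 7e8))
  expect_match(names(cfg$densities), "mM")
})
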