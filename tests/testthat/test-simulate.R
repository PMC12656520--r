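test_that("trial configuration validates its invariants", {
  expect_s3_class(trial_config(), "trial_config")
  expect_error(trial_config(true_sigma_psib = 0),
               class = "seedhtt_schema_error")
  expect_error(trial_config(scoring_interval = 9, census_end = 168),
               class = "seedhtt_schema_error")
  expect_error(trial_config(water_potentials = c(0.2, -0.2)),
               class = "seedhtt_schema_error")
})

test_that("simulation is deterministic and stable under added replicates", {
  cfg <- trial_config(temperatures = c(20, 30),
                      water_potentials = c(0, -0.4), n_reps = 2,
                      rng_seed = 123)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a, b)
  # adding replicates must not reshuffle existing dishes
  cfg4 <- trial_config(temperatures = c(20, 30),
                       water_potentials = c(0, -0.4), n_reps = 4,
                       rng_seed = 123)
  c4 <- simulate_trial(cfg4)
  sub <- c4[c4$replicate <= 2, ]
  rownames(sub) <- NULL
  expect_equal(sub$cum_germinated, a$cum_germinated)
})

test_that("counts are cumulative, bounded and censored", {
  trial <- simulate_trial(trial_config(rng_seed = 2, n_reps = 2))
  expect_true(all(trial$cum_germinated >= 0 &
                    trial$cum_germinated <= trial$n_sown))
  key <- paste(trial$temperature, trial$water_potential, trial$replicate)
  for (k in unique(key)) {
    expect_true(all(diff(trial$cum_germinated[key == k]) >= 0))
  }
  expect_equal(max(trial$time), 168)
})

test_that("water far below every seed's threshold gives zero germination", {
  cfg <- trial_config(true_psi_b50 = -0.6, true_sigma_psib = 0.1,
                      temperatures = c(25),
                      water_potentials = -0.6 - 5 * 0.1,
                      n_reps = 4, rng_seed = 8)
  trial <- simulate_trial(cfg)
  expect_equal(max(trial$cum_germinated), 0)
})

test_that("final fractions converge to the censored closed form", {
  # psi = 0, T far above Tb, long census: fraction -> Phi((0-psi_b50)/sigma)
  cfg <- trial_config(true_theta_HT = 500, true_Tb = 10,
                      true_psi_b50 = -0.6, true_sigma_psib = 0.2,
                      temperatures = 35, water_potentials = 0,
                      n_seeds = 20000, n_reps = 1, census_end = 10000,
                      scoring_interval = 8, rng_seed = 21)
  trial <- simulate_trial(cfg)
  frac <- max(trial$cum_germinated) / 20000
  expect_equal(frac, pnorm(0.6 / 0.2), tolerance = 0.01)
})

test_that("finer scoring reduces the discretization error of theta_HT", {
  base <- list(temperatures = seq(15, 45, 5),
               water_potentials = seq(0, -0.8, -0.2),
               n_seeds = 50, n_reps = 4)
  err <- function(interval, seed) {
    cfg <- do.call(trial_config, c(base, list(scoring_interval = interval,
                                              rng_seed = seed)))
    pct <- percentile_times(simulate_trial(cfg))
    abs(suppressWarnings(fit_htt(pct))$theta_HT - 500)
  }
  seeds <- 300 + 1:5
  e1 <- vapply(seeds, function(s) err(1, s), 0)
  e8 <- vapply(seeds, function(s) err(8, s), 0)
  expect_lte(median(e1), median(e8))
})

test_that("the recovery harness reports coverage and survives failures", {
  cfg <- trial_config(temperatures = c(15, 25, 35),
                      water_potentials = c(0, -0.3, -0.6),
                      n_seeds = 40, n_reps = 2, rng_seed = 50)
  rep <- recovery_suite(cfg, n_runs = 3)
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep$runs), 3)
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 1))
  # zero tolerance can never be met by noisy estimates
  rep0 <- recovery_suite(cfg, n_runs = 2,
                         tolerances = list(theta_HT = 0, Tb = 0,
                                           psi_b50 = 0, sigma_psib = 0))
  expect_equal(rep0$coverage, 0)
})
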