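test_that("htt_time evaluates the threshold model and its boundaries", {
  # proportionality: doubling (T - Tb) halves the time
  expect_equal(htt_time(500, 10, -0.6, 20, 0), 2 * htt_time(500, 10, -0.6, 30, 0))
  # at either threshold, no germination
  expect_true(is.na(htt_time(500, 10, -0.6, 25, -0.6)))
  expect_true(is.na(htt_time(500, 10, -0.6, 10, 0)))
  expect_true(is.na(htt_time(500, 10, -0.6, 9, -0.7)))
})

test_that("noiseless generative data is recovered within 1%", {
  pct <- exact_htt_percentiles(500, 10, -0.6, 0.2, temps = seq(15, 45, 5),
                               psis = seq(0, -0.8, by = -0.2))
  fit <- suppressWarnings(fit_htt(pct))
  expect_equal(fit$theta_HT, 500, tolerance = 0.01)
  expect_equal(fit$Tb, 10, tolerance = 0.01)
  expect_equal(fit$psi_b50, -0.6, tolerance = 0.01)
  expect_equal(fit$sigma_psib, 0.2, tolerance = 0.01)
  expect_gte(fit$diagnostics$r_squared, 0.999)
})

test_that("fixed-Tb mode reproduces the supplied-Tb workflow", {
  pct <- exact_htt_percentiles(500, 10, -0.6, 0.2, temps = seq(15, 40, 5),
                               psis = c(0, -0.3, -0.6))
  fit <- fit_htt(pct, fixed_Tb = 10)
  expect_true(fit$fixed_Tb)
  expect_equal(fit$Tb, 10)
  expect_equal(fit$theta_HT, 500, tolerance = 0.005)
  expect_error(fit_htt(pct, fixed_Tb = 20), class = "seedhtt_data_error")
})

test_that("a temperature window restricts the range used", {
  pct <- exact_htt_percentiles(500, 10, -0.6, 0.2, temps = seq(15, 45, 5),
                               psis = c(0, -0.3, -0.6))
  fit <- suppressWarnings(fit_htt(pct, temp_window = c(15, 30)))
  expect_equal(fit$temp_range_used, c(15, 30))
  expect_equal(fit$theta_HT, 500, tolerance = 0.01)
})

test_that("fixed-temperature slices reduce to the hydrotime model", {
  theta_HT <- 500; Tb <- 10
  pct <- exact_htt_percentiles(theta_HT, Tb, -0.6, 0.2,
                               temps = c(15, 20, 25, 30),
                               psis = seq(0, -0.8, by = -0.2))
  for (T in c(15, 20, 30)) {
    slice <- pct[pct$temperature == T, , drop = FALSE]
    fit <- fit_hydrotime(slice)
    expect_equal(fit$theta_H, theta_HT / (T - Tb),
                 tolerance = 0.05)
  }
})

test_that("predicted time courses are monotone with the right asymptote", {
  pct <- exact_htt_percentiles(500, 10, -0.6, 0.2, temps = seq(15, 40, 5),
                               psis = c(0, -0.3, -0.6))
  fit <- suppressWarnings(fit_htt(pct))
  times <- seq(8, 168, by = 8)
  for (psi in c(0, -0.4)) {
    g <- predict_time_course(fit, 25, psi, times)
    expect_true(all(diff(g) >= 0))
    expect_true(all(g >= 0 & g <= 1))
    # asymptote = germinable fraction, invariant to the time grid
    expect_equal(predict_time_course(fit, 25, psi, 1e9),
                 germinable_fraction(fit, psi), tolerance = 1e-6)
  }
  # median time maps back to g = 0.5
  t50 <- htt_time(fit$theta_HT, fit$Tb, fit$psi_b50, 25, 0)
  expect_equal(predict_time_course(fit, 25, 0, t50), 0.5, tolerance = 1e-9)
  # below Tb nothing germinates
  expect_equal(predict_time_course(fit, fit$Tb - 1, 0, times),
               rep(0, length(times)))
})

test_that("bootstrap SEM over replicates is reproducible and positive", {
  cfg <- trial_config(temperatures = c(15, 25, 35),
                      water_potentials = c(0, -0.3, -0.6),
                      n_seeds = 30, n_reps = 3, rng_seed = 5)
  trial <- simulate_trial(cfg)
  pct <- percentile_times(trial)
  f1 <- suppressWarnings(fit_htt(pct, counts = trial, n_boot = 25,
                                 boot_seed = 9))
  f2 <- suppressWarnings(fit_htt(pct, counts = trial, n_boot = 25,
                                 boot_seed = 9))
  expect_equal(f1$bootstrap, f2$bootstrap)
  expect_gt(f1$diagnostics$sem, 0)
  expect_length(f1$bootstrap, 25)
})

test_that("insufficient designs error cleanly", {
  pct <- exact_htt_percentiles(500, 10, -0.6, 0.2, temps = c(20, 30),
                               psis = c(0, -0.3))
  expect_error(suppressWarnings(fit_htt(pct)),
               class = "seedhtt_data_error")
  one_psi <- exact_htt_percentiles(500, 10, -0.6, 0.2,
                                   temps = c(15, 20, 25, 30), psis = 0)
  expect_error(suppressWarnings(fit_htt(one_psi)),
               class = "seedhtt_data_error")
})
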