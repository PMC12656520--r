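test_that("reading validates the schema and count monotonicity", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_counts(c(0, 3, 7))
  write_germination_counts(validate_counts(df), path)
  rd <- read_germination_counts(path)
  expect_equal(nrow(rd), 3)
  expect_equal(rd$cum_germinated, c(0, 3, 7))

  bad <- make_counts(c(5, 4), times = c(8, 16))
  expect_error(validate_counts(bad), class = "seedhtt_data_error")
  expect_error(validate_counts(bad), "decreasing cumulative count")

  nohdr <- df
  names(nohdr)[names(nohdr) == "cum_germinated"] <- "germ"
  expect_error(validate_counts(nohdr), class = "seedhtt_schema_error")
})

test_that("simulated trials round-trip through the file format", {
  trial <- simulate_trial(trial_config(temperatures = c(20, 30),
                                       water_potentials = c(0, -0.4),
                                       n_reps = 2, rng_seed = 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_germination_counts(trial, path)
  back <- read_germination_counts(path)
  expect_equal(back$cum_germinated, trial$cum_germinated)
  expect_equal(back$time, trial$time)
  expect_equal(back$water_potential, trial$water_potential)
})

test_that("plateau truncation keeps the first time the maximum is reached", {
  tc <- validate_counts(make_counts(c(0, 3, 7, 7, 7)))
  tr <- truncate_plateau(tc)
  expect_equal(tr$cum_germinated, c(0, 3, 7))
  expect_equal(tr$time, c(8, 16, 24))
  # idempotent
  expect_equal(truncate_plateau(tr)$cum_germinated, tr$cum_germinated)
  # strictly increasing course unchanged
  inc <- validate_counts(make_counts(c(1, 3, 7)))
  expect_equal(truncate_plateau(inc)$cum_germinated, c(1, 3, 7))
  # all-zero course: single point retained and flagged
  z <- validate_counts(make_counts(c(0, 0, 0, 0)))
  tz <- truncate_plateau(z)
  expect_equal(nrow(tz), 1)
  expect_equal(tz$time, 32)
  expect_equal(nrow(attr(tz, "non_germinating")), 1)
})

test_that("final germination pools counts, not replicate percentages", {
  expect_equal(final_germination(
    validate_counts(make_counts(c(10, 39))))$G, 78)
  expect_equal(final_germination(
    validate_counts(make_counts(c(0, 0))))$G, 0)
  # two dishes of different sizes: count-weighted pool
  a <- make_counts(c(10, 20), n_sown = 100, replicate = 1)
  b <- make_counts(c(5, 10), n_sown = 20, replicate = 2)
  pooled <- final_germination(validate_counts(rbind(a, b)))
  expect_equal(pooled$G, 100 * 30 / 120)
  expect_false(isTRUE(all.equal(pooled$G, mean(c(20, 50)))))
})

test_that("time_to_fraction interpolates linearly and flags the unreachable", {
  # fractions 0.4 @ 24 h and 0.6 @ 32 h bracket g = 0.5 at 28 h
  expect_equal(time_to_fraction(c(8, 16, 24, 32), c(0, 0.1, 0.4, 0.6), 0.5),
               28)
  expect_true(is.na(time_to_fraction(c(8, 16), c(0.2, 0.35), 0.5)))
  expect_error(time_to_fraction(c(8, 16), c(0.2, 0.4), 1.2),
               class = "seedhtt_data_error")
  # non-decreasing in g along one curve
  tg <- vapply(seq(0.05, 0.55, by = 0.05), function(g)
    time_to_fraction(c(8, 16, 24, 32), c(0, 0.1, 0.4, 0.6), g), 0)
  expect_true(all(diff(tg) >= 0))
})

test_that("percentile times match the generating quantiles within a scoring interval", {
  # noiseless check: large dishes, fine discretization
  cfg <- trial_config(true_theta_HT = 500, true_Tb = 10,
                      true_psi_b50 = -0.6, true_sigma_psib = 0.2,
                      temperatures = c(20, 25, 30),
                      water_potentials = c(0, -0.2),
                      n_seeds = 4000, n_reps = 1, scoring_interval = 8,
                      rng_seed = 11)
  pct <- percentile_times(simulate_trial(cfg))
  for (i in seq_len(nrow(pct))) {
    if (!is.finite(pct$t_g[i])) next
    psi_bg <- -0.6 + 0.2 * qnorm(pct$g[i])
    t_true <- 500 / ((pct$water_potential[i] - psi_bg) *
                       (pct$temperature[i] - 10))
    expect_lt(abs(pct$t_g[i] - t_true), 8)
  }
})

test_that("zero-germination treatments are excluded with a record", {
  cfg <- trial_config(temperatures = c(10, 25),
                      water_potentials = c(0, -1.2),
                      n_reps = 2, rng_seed = 3)
  pct <- percentile_times(simulate_trial(cfg))
  excl <- attr(pct, "excluded")
  # 10 degC equals Tb: no germination at any water potential there
  expect_true(all(c(10) %in% excl$temperature))
  expect_false(any(pct$temperature == 10))
})
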