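# Synthetic germination trials generated from the hydrothermal time model
# itself: each seed carries a normally distributed base water potential,
# germinates at t = theta_HT/((psi - psi_b)(T - Tb)) when both thresholds
# are exceeded, and is observed on a discrete scoring grid with right
# censoring at the end of the test. Used to validate every fitter by
# parameter recovery without external data.

#' Configuration of a synthetic germination trial
#'
#' Bundles the generating hydrothermal-time parameters and the trial design.
#' The defaults mirror a full factorial sesame-type germination assay:
#' eight constant temperatures (10-45 degC), seven water potentials
#' (0 to -1.2 MPa imposed with PEG-6000), four replicate dishes of 50 seeds,
#' scoring every 8 h for 7 days (168 h).
#'
#' @param true_theta_HT hydrothermal time constant (MPa degC h).
#' @param true_Tb base temperature (degC).
#' @param true_psi_b50 median base water potential (MPa).
#' @param true_sigma_psib between-seed SD of base water potential (MPa).
#' @param temperatures trial temperatures (degC).
#' @param water_potentials trial water potentials (MPa, <= 0).
#' @param n_seeds seeds per dish.
#' @param n_reps replicate dishes per treatment.
#' @param scoring_interval hours between counts; must divide
#'   \code{census_end}.
#' @param census_end end of the test (hours).
#' @param rng_seed master RNG seed; per-dish streams are derived from it so
#'   adding replicates never reshuffles earlier dishes.
#' @param cultivar label carried into the output.
#' @return An object of class \code{trial_config} (a validated list).
#' @export
trial_config <- function(true_theta_HT = 500, true_Tb = 10,
                         true_psi_b50 = -0.6, true_sigma_psib = 0.2,
                         temperatures = seq(10, 45, by = 5),
                         water_potentials = seq(0, -1.2, by = -0.2),
                         n_seeds = 50, n_reps = 4,
                         scoring_interval = 8, census_end = 168,
                         rng_seed = 1L, cultivar = "synthetic") {
  cfg <- list(true_theta_HT = true_theta_HT, true_Tb = true_Tb,
              true_psi_b50 = true_psi_b50,
              true_sigma_psib = true_sigma_psib,
              temperatures = temperatures,
              water_potentials = water_potentials,
              n_seeds = n_seeds, n_reps = n_reps,
              scoring_interval = scoring_interval, census_end = census_end,
              rng_seed = as.integer(rng_seed), cultivar = cultivar)
  if (cfg$true_theta_HT <= 0 || cfg$true_sigma_psib <= 0) {
    abort_schema("scale parameters true_theta_HT and true_sigma_psib must be > 0")
  }
  if (any(cfg$water_potentials > 0)) {
    abort_schema("water_potentials must be <= 0 MPa")
  }
  if (cfg$scoring_interval <= 0 ||
      abs(cfg$census_end / cfg$scoring_interval -
            round(cfg$census_end / cfg$scoring_interval)) > 1e-9) {
    abort_schema("scoring_interval must be positive and divide census_end")
  }
  if (cfg$n_seeds < 1 || cfg$n_reps < 1) {
    abort_schema("n_seeds and n_reps must be >= 1")
  }
  structure(cfg, class = "trial_config")
}

# Deterministic per-dish seed: independent of n_reps and of grid sizes so
# extending the design leaves existing dishes untouched.
dish_seed <- function(master, ti, wi, rep) {
  (abs(master) + 97L * ti + 1009L * wi + 100003L * rep) %%
    .Machine$integer.max
}

#' Simulate a germination trial from the hydrothermal time model
#'
#' For every dish, draws one base water potential per seed from
#' Normal(psi_b50, sigma_psib); a seed germinates at
#' theta_HT/((psi - psi_b)(T - Tb)) hours when psi > psi_b and T > Tb, and
#' never otherwise. Germination times are observed on the scoring grid (a
#' seed is first seen germinated at the next count after its true time, so
#' times round up) and right-censored at the end of the test. Output is
#' fully reproducible from the configuration's seed.
#'
#' @param cfg a [trial_config()].
#' @return A \code{germination_counts} data frame (one row per dish x
#'   scoring time) in the same schema as [read_germination_counts()].
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  times <- seq(cfg$scoring_interval, cfg$census_end,
               by = cfg$scoring_interval)
  parts <- list()
  for (ti in seq_along(cfg$temperatures)) {
    T <- cfg$temperatures[ti]
    for (wi in seq_along(cfg$water_potentials)) {
      psi <- cfg$water_potentials[wi]
      for (r in seq_len(cfg$n_reps)) {
        set.seed(dish_seed(cfg$rng_seed, ti, wi, r))
        psi_b <- stats::rnorm(cfg$n_seeds, cfg$true_psi_b50,
                              cfg$true_sigma_psib)
        t_true <- ifelse(T > cfg$true_Tb & psi > psi_b,
                         cfg$true_theta_HT /
                           ((psi - psi_b) * (T - cfg$true_Tb)),
                         Inf)
        t_obs <- ceiling(t_true / cfg$scoring_interval) *
          cfg$scoring_interval
        cum <- vapply(times, function(tt) sum(t_obs <= tt), 0L)
        parts[[length(parts) + 1L]] <- data.frame(
          cultivar = cfg$cultivar, temperature = T, water_potential = psi,
          replicate = r, n_sown = cfg$n_seeds, time = times,
          cum_germinated = cum, stringsAsFactors = FALSE)
      }
    }
  }
  validate_counts(do.call(rbind, parts))
}

#' Parameter-recovery study over repeated synthetic trials
#'
#' Runs \code{n_runs} independently seeded trials from one configuration,
#' pushes each through the standard pipeline (percentile extraction then
#' hydrothermal fit), and summarizes how well the generating parameters are
#' recovered: per-parameter bias, root-mean-square error, and the fraction
#' of runs in which every parameter lands within its stated tolerance
#' (coverage). Individual fitter failures are recorded per run, not fatal.
#'
#' @param cfg a [trial_config()]; run \code{i} uses
#'   \code{rng_seed + i}.
#' @param n_runs number of simulated trials.
#' @param tolerances list with \code{theta_HT} (relative), \code{Tb},
#'   \code{psi_b50}, \code{sigma_psib} (absolute) tolerances.
#' @param g_levels,basis passed to [percentile_times()].
#' @param ... further arguments to [fit_htt()] (e.g. \code{temp_window}).
#' @return Object of class \code{recovery_report}: \code{runs} (one row per
#'   run with estimates, errors, in-tolerance flags and any failure
#'   message), \code{summary} (bias/RMSE per parameter), \code{coverage}
#'   (joint fraction within all tolerances) and the inputs.
#' @export
recovery_suite <- function(cfg, n_runs = 20,
                           tolerances = list(theta_HT = 0.15, Tb = 1.5,
                                             psi_b50 = 0.05,
                                             sigma_psib = 0.05),
                           g_levels = seq(0.1, 0.9, by = 0.1),
                           basis = "sown", ...) {
  stopifnot(inherits(cfg, "trial_config"), n_runs >= 1)
  runs <- lapply(seq_len(n_runs), function(i) {
    cfg_i <- cfg
    cfg_i$rng_seed <- cfg$rng_seed + i
    out <- data.frame(run = i, seed = cfg_i$rng_seed,
                      theta_HT = NA_real_, Tb = NA_real_,
                      psi_b50 = NA_real_, sigma_psib = NA_real_,
                      r_squared = NA_real_, ok = FALSE, note = "",
                      stringsAsFactors = FALSE)
    fit <- tryCatch({
      trial <- simulate_trial(cfg_i)
      pct <- percentile_times(trial, g_levels = g_levels, basis = basis)
      suppressWarnings(fit_htt(pct, ...))
    }, seedhtt_error = function(e) e)
    if (inherits(fit, "hydrothermal_fit")) {
      out$theta_HT <- fit$theta_HT
      out$Tb <- fit$Tb
      out$psi_b50 <- fit$psi_b50
      out$sigma_psib <- fit$sigma_psib
      out$r_squared <- fit$diagnostics$r_squared
      out$ok <- TRUE
    } else {
      out$note <- conditionMessage(fit)
    }
    out
  })
  runs <- do.call(rbind, runs)
  runs$within_theta <- runs$ok &
    abs(runs$theta_HT - cfg$true_theta_HT) <=
      tolerances$theta_HT * cfg$true_theta_HT
  runs$within_Tb <- runs$ok & abs(runs$Tb - cfg$true_Tb) <= tolerances$Tb
  runs$within_psi_b50 <- runs$ok &
    abs(runs$psi_b50 - cfg$true_psi_b50) <= tolerances$psi_b50
  runs$within_sigma <- runs$ok &
    abs(runs$sigma_psib - cfg$true_sigma_psib) <= tolerances$sigma_psib
  runs$within_all <- runs$within_theta & runs$within_Tb &
    runs$within_psi_b50 & runs$within_sigma
  truth <- c(theta_HT = cfg$true_theta_HT, Tb = cfg$true_Tb,
             psi_b50 = cfg$true_psi_b50, sigma_psib = cfg$true_sigma_psib)
  summ <- do.call(rbind, lapply(names(truth), function(p) {
    est <- runs[[p]][runs$ok]
    data.frame(parameter = p, truth = truth[[p]],
               bias = mean(est) - truth[[p]],
               rmse = sqrt(mean((est - truth[[p]])^2)),
               coverage = mean(runs[[paste0(
                 "within_", switch(p, theta_HT = "theta", Tb = "Tb",
                                   psi_b50 = "psi_b50",
                                   sigma_psib = "sigma"))]]),
               stringsAsFactors = FALSE)
  }))
  structure(class = "recovery_report", list(
    config = cfg, tolerances = tolerances, runs = runs, summary = summ,
    coverage = mean(runs$within_all), n_failed = sum(!runs$ok)))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d simulated trials (%d failed)\n",
              nrow(x$runs), x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("Joint coverage within tolerances: %.2f\n", x$coverage))
  invisible(x)
}
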