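# Hydrothermal time model over the full temperature x water-potential grid:
#   theta_HT = (psi - psi_b(g)) (T - Tb) t(g)
# with per-seed base water potentials Normal(psi_b50, sigma_psib) and a
# common base temperature Tb. Linearized by probit:
#   probit(g) = (psi - theta_HT/((T - Tb) t(g)) - psi_b50) / sigma_psib
# so for candidate (theta_HT, Tb) the model is a straight line of probit(g)
# on x = psi - theta_HT/((T - Tb) t(g)); the candidates are chosen to
# maximize that regression's R-squared.

#' Hydrothermal time to fraction g
#'
#' Direct evaluation of the hydrothermal time model:
#' t(g) = theta_HT / ((psi - psi_b) (T - Tb)). Below either threshold
#' (temperature at or below Tb, water potential at or below the seed
#' fraction's base water potential) germination never occurs and \code{NA}
#' is returned.
#'
#' @param theta_HT hydrothermal time constant (MPa degC h).
#' @param Tb base temperature (degC).
#' @param psi_b base water potential of the seed fraction considered (MPa).
#' @param temperature temperature (degC); vectorized.
#' @param psi water potential (MPa); vectorized.
#' @return Time in hours, \code{NA} where no germination is predicted.
#' @examples
#' htt_time(213.4, 13.096, -0.575, temperature = 25, psi = 0)  # ~31.2 h
#' @export
htt_time <- function(theta_HT, Tb, psi_b, temperature, psi) {
  ifelse(temperature > Tb & psi > psi_b,
         theta_HT / ((psi - psi_b) * (temperature - Tb)),
         NA_real_)
}

# Probit R-squared for a candidate (theta_HT, Tb) on prepared vectors.
htt_r2 <- function(theta_HT, Tb, psi, temperature, t_g, y) {
  x <- psi - theta_HT / ((temperature - Tb) * t_g)
  linreg(x, y)$r_squared
}

#' Fit the hydrothermal time model
#'
#' Estimates (theta_HT, Tb, psi_b50, sigma_psib) from percentile
#' germination times spanning several temperatures and water potentials.
#' For each candidate pair the probit of each observed fraction is
#' regressed on psi - theta_HT/((T - Tb) t(g)); the pair maximizing the
#' regression R-squared wins, and psi_b50 = -intercept/slope,
#' sigma_psib = 1/slope come from the winning line. All reachable g levels
#' at every treatment enter the regression.
#'
#' The outer search runs Tb over a 0.5 degC grid on [0, min(T) - 1], each
#' with an inner log-grid plus golden-section search over theta_HT, and
#' finishes with a nested continuous refinement of both (relative tolerance
#' about 1e-4). \code{fixed_Tb} skips the outer search, reproducing the
#' workflow where Tb is supplied from a thermal time analysis.
#'
#' @param percentiles a \code{percentile_times} data frame (one cultivar)
#'   spanning >= 3 temperatures and >= 2 water potentials with germination.
#' @param fixed_Tb optional fixed base temperature (degC).
#' @param temp_window optional \code{c(lo, hi)} restricting the
#'   temperatures used, for lots whose germination is poor outside a range.
#' @param theta_range search bracket for theta_HT (MPa degC h).
#' @param n_grid coarse grid size of the inner theta_HT search.
#' @param counts optional \code{germination_counts} data frame (the data
#'   the percentiles came from); when supplied, the standard error of
#'   theta_HT is estimated by a nonparametric bootstrap over replicate
#'   dishes.
#' @param n_boot bootstrap resamples (default 200).
#' @param boot_seed RNG seed for the bootstrap.
#' @return Object of class \code{hydrothermal_fit}: \code{theta_HT},
#'   \code{Tb}, \code{psi_b50}, \code{sigma_psib}, \code{temp_range_used},
#'   \code{diagnostics} (probit \code{r_squared}, \code{rmse} in percentage
#'   points, \code{n_obs}, \code{sem} of theta_HT when bootstrapped) and,
#'   when bootstrapped, \code{bootstrap} (the resampled theta_HT values).
#' @export
fit_htt <- function(percentiles, fixed_Tb = NULL, temp_window = NULL,
                    theta_range = c(1, 1e5), n_grid = 40,
                    counts = NULL, n_boot = 200, boot_seed = 1L) {
  pct <- as.data.frame(percentiles)
  if (length(unique(pct$cultivar)) > 1) {
    abort_data("fit_htt expects percentiles of a single cultivar")
  }
  if (!is.null(temp_window)) {
    pct <- pct[pct$temperature >= temp_window[1] &
                 pct$temperature <= temp_window[2], , drop = FALSE]
  }
  use <- pct[is.finite(pct$t_g) & pct$g > 0 & pct$g < 1, , drop = FALSE]
  temps <- sort(unique(use$temperature))
  if (length(temps) < 3) {
    abort_data("hydrothermal fit needs germination at >= 3 temperatures")
  }
  if (length(unique(use$water_potential)) < 2) {
    abort_data("hydrothermal fit needs germination at >= 2 water potentials")
  }
  y <- stats::qnorm(use$g)
  inner <- function(Tb) {
    search_theta(function(lth)
      htt_r2(exp(lth), Tb, use$water_potential, use$temperature, use$t_g, y),
      theta_range[1], theta_range[2], n_grid)
  }
  boundary <- FALSE
  if (is.null(fixed_Tb)) {
    tb_max <- min(temps) - 1
    if (tb_max < 0) abort_data("lowest usable temperature below 1 degC")
    tb_grid <- seq(0, tb_max, by = 0.5)
    prof <- suppressWarnings(lapply(tb_grid, inner))
    vals <- vapply(prof, `[[`, 0, "value")
    i <- which.max(vals)
    if (i == 1 || i == length(tb_grid)) {
      warn_boundary(sprintf("Tb search optimum at grid edge (%.1f degC)",
                            tb_grid[i]))
      boundary <- TRUE
      Tb <- tb_grid[i]
      sr <- prof[[i]]
    } else {
      opt <- suppressWarnings(stats::optimize(
        function(Tb) inner(Tb)$value,
        c(tb_grid[i - 1], tb_grid[i + 1]), maximum = TRUE, tol = 1e-3))
      Tb <- opt$maximum
      sr <- suppressWarnings(inner(Tb))
      if (sr$value < vals[i]) {
        Tb <- tb_grid[i]
        sr <- prof[[i]]
      }
    }
    boundary <- boundary || sr$boundary
  } else {
    Tb <- fixed_Tb
    if (Tb >= min(temps)) {
      abort_data("fixed Tb must lie below the lowest usable temperature")
    }
    sr <- inner(Tb)
    boundary <- sr$boundary
  }
  theta <- exp(sr$log_theta)
  x <- use$water_potential - theta / ((use$temperature - Tb) * use$t_g)
  reg <- linreg(x, y)
  if (!is.finite(reg$slope) || reg$slope <= 0) {
    abort_convergence("non-positive probit slope: sigma_psib not identifiable")
  }
  g_hat <- stats::pnorm(reg$intercept + reg$slope * x)
  fit <- structure(class = "hydrothermal_fit", list(
    theta_HT = theta,
    Tb = Tb,
    psi_b50 = -reg$intercept / reg$slope,
    sigma_psib = 1 / reg$slope,
    fixed_Tb = !is.null(fixed_Tb),
    temp_range_used = range(temps),
    boundary = boundary,
    diagnostics = list(r_squared = reg$r_squared,
                       rmse = sqrt(mean((100 * use$g - 100 * g_hat)^2)),
                       n_obs = nrow(use), sem = NA_real_)))
  if (!is.null(counts) && n_boot > 0) {
    bt <- htt_bootstrap(counts, percentiles, fixed_Tb = fixed_Tb,
                        temp_window = temp_window, theta_range = theta_range,
                        n_grid = n_grid, n_boot = n_boot, seed = boot_seed)
    fit$bootstrap <- bt
    fit$diagnostics$sem <- stats::sd(bt, na.rm = TRUE)
  }
  fit
}

# Nonparametric bootstrap of theta_HT: within every treatment, replicate
# dishes are resampled with replacement, percentile times are recomputed
# with the same settings as the original table, and the model is refitted.
htt_bootstrap <- function(counts, percentiles, fixed_Tb, temp_window,
                          theta_range, n_grid, n_boot, seed) {
  df <- validate_counts(counts)
  g_levels <- attr(percentiles, "g_levels") %||% seq(0.1, 0.9, by = 0.1)
  basis <- attr(percentiles, "basis") %||% "sown"
  min_g <- attr(percentiles, "min_germinated") %||% 1
  tkey <- treatment_key(df)
  groups <- lapply(split(seq_len(nrow(df)), tkey), function(idx) {
    split(idx, df$replicate[idx])
  })
  vapply(seq_len(n_boot), function(b) {
    set.seed((seed + 104729L * b) %% .Machine$integer.max)
    parts <- list()
    lab <- 0L
    for (reps in groups) {
      pick <- sample.int(length(reps), length(reps), replace = TRUE)
      for (j in pick) {
        lab <- lab + 1L
        rows <- df[reps[[j]], , drop = FALSE]
        # fresh label so the same dish drawn twice stays two dishes
        rows$replicate <- lab
        parts[[length(parts) + 1L]] <- rows
      }
    }
    boot_df <- do.call(rbind, parts)
    tryCatch({
      p <- percentile_times(boot_df, g_levels = g_levels, basis = basis,
                            min_germinated = min_g)
      f <- suppressWarnings(
        fit_htt(p, fixed_Tb = fixed_Tb, temp_window = temp_window,
                theta_range = theta_range, n_grid = n_grid, counts = NULL))
      f$theta_HT
    }, seedhtt_error = function(e) NA_real_, error = function(e) NA_real_)
  }, 0)
}

#' @export
print.hydrothermal_fit <- function(x, ...) {
  cat("Hydrothermal time fit\n")
  cat(sprintf(
    "  theta_HT = %.1f MPa degC h,  Tb = %.3f degC%s\n", x$theta_HT, x$Tb,
    if (x$fixed_Tb) " (fixed)" else ""))
  cat(sprintf("  psi_b50 = %.3f MPa,  sigma_psib = %.3f MPa\n",
              x$psi_b50, x$sigma_psib))
  cat(sprintf("  temperatures used: %g-%g degC\n", x$temp_range_used[1],
              x$temp_range_used[2]))
  cat(sprintf("  probit R2 = %.4f, RMSE = %.2f %%G, n = %d",
              x$diagnostics$r_squared, x$diagnostics$rmse,
              x$diagnostics$n_obs))
  if (is.finite(x$diagnostics$sem)) {
    cat(sprintf(", SEM(theta_HT) = %.2f", x$diagnostics$sem))
  }
  cat("\n")
  invisible(x)
}

#' Predicted cumulative germination time course
#'
#' Inverts the fitted hydrothermal time model to the cumulative germinated
#' fraction at each time:
#' g(t) = Phi((psi - theta_HT/((T - Tb) t) - psi_b50)/sigma_psib),
#' which rises monotonically towards the asymptote
#' Phi((psi - psi_b50)/sigma_psib), the fraction of seeds whose base water
#' potential lies below psi.
#'
#' @param fit a \code{hydrothermal_fit}.
#' @param temperature temperature in degC (single value).
#' @param psi water potential in MPa (single value).
#' @param times vector of times (hours).
#' @return Cumulative germinated fractions, one per time; all zero when
#'   \code{temperature <= Tb}.
#' @export
predict_time_course <- function(fit, temperature, psi, times) {
  stopifnot(inherits(fit, "hydrothermal_fit"))
  if (temperature <= fit$Tb) return(rep(0, length(times)))
  out <- numeric(length(times))
  pos <- times > 0
  z <- (psi - fit$theta_HT / ((temperature - fit$Tb) * times[pos]) -
          fit$psi_b50) / fit$sigma_psib
  out[pos] <- stats::pnorm(z)
  out
}
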