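# Hydrotime model. At one temperature, seed i germinates at water potential
# psi only if psi exceeds its base water potential psi_b(i), and reaches
# fraction g at time t(g) satisfying
#   theta_H = (psi - psi_b(g)) t(g).
# psi_b varies between seeds as Normal(psi_b50, sigma_psib), so
#   probit(g) = (psi - theta_H/t(g) - psi_b50) / sigma_psib
# is linear in x = psi - theta_H/t(g). The fit nests that probit regression
# inside a one-dimensional search over theta_H.

#' Probit regression design for the hydrotime model
#'
#' Builds the paired regression vectors of the linearized hydrotime model
#' for a candidate hydrotime constant: y = probit(g) (the standard normal
#' quantile of the germinated fraction) and x = psi - theta_H / t(g).
#' Fractions of exactly 0 or 1 have infinite probits and cannot enter.
#'
#' @param g germinated fractions, strictly inside (0, 1).
#' @param psi water potentials (MPa) aligned with \code{g}.
#' @param t_g times to fraction g (hours) aligned with \code{g}.
#' @param theta_H candidate hydrotime constant (MPa h).
#' @return List with vectors \code{x} and \code{y}.
#' @export
probit_design <- function(g, psi, t_g, theta_H) {
  ok <- is.finite(g) & is.finite(psi) & is.finite(t_g) &
    g > 0 & g < 1 & t_g > 0
  if (!any(ok)) abort_data("no usable (g, psi, t_g) observations")
  list(x = psi[ok] - theta_H / t_g[ok], y = stats::qnorm(g[ok]))
}

# Shared 1-d search: coarse log-spaced grid over [lo, hi], then golden
# section (optimize) between the bracketing neighbours of the best grid
# point, on the log scale, to a relative tolerance of about 1e-4.
search_theta <- function(objective, lo, hi, n_grid = 40) {
  lgrid <- seq(log(lo), log(hi), length.out = n_grid)
  vals <- vapply(lgrid, objective, 0)
  i <- which.max(vals)
  if (i == 1 || i == n_grid) {
    warn_boundary(sprintf(
      "time-constant search optimum at grid edge (theta = %.4g)",
      exp(lgrid[i])))
    return(list(log_theta = lgrid[i], value = vals[i], boundary = TRUE))
  }
  opt <- stats::optimize(objective, c(lgrid[i - 1], lgrid[i + 1]),
                         maximum = TRUE, tol = 1e-4)
  if (opt$objective >= vals[i]) {
    list(log_theta = opt$maximum, value = opt$objective, boundary = FALSE)
  } else {
    list(log_theta = lgrid[i], value = vals[i], boundary = FALSE)
  }
}

#' Fit the hydrotime model at one temperature
#'
#' Grid search over the hydrotime constant theta_H (log-spaced over
#' \code{theta_range}, refined by golden-section search to a relative
#' tolerance of 1e-4), maximizing the R-squared of the probit regression of
#' germinated fraction on psi - theta_H/t(g). The winning regression gives
#' psi_b50 = -intercept/slope and sigma_psib = 1/slope.
#'
#' All reachable percentile observations (every g level at every water
#' potential) enter the regression. The fit also reports predicted and
#' observed final germination at a reference water potential: predicted
#' G = 100 Phi((psi_ref - psi_b50)/sigma_psib) from the fitted base-water-
#' potential distribution, observed G from the pooled data.
#'
#' @param percentiles a \code{percentile_times} data frame restricted to a
#'   single temperature (and cultivar), spanning two or more water
#'   potentials.
#' @param theta_range search bracket for theta_H in MPa h; the default
#'   c(0.1, 500) covers reported sesame values (3.4-81.9 MPa h) with wide
#'   margin.
#' @param psi_ref reference water potential for predicted/observed G;
#'   defaults to the highest (least negative) water potential present.
#' @param n_grid number of coarse grid points.
#' @return Object of class \code{hydrotime_fit}: \code{theta_H} (MPa h),
#'   \code{psi_b50} (MPa), \code{sigma_psib} (MPa), \code{predicted_G},
#'   \code{observed_G} (percent, at \code{psi_ref}), \code{temperature},
#'   \code{diagnostics} (probit \code{r_squared}, \code{rmse} in percentage
#'   points of germination, \code{n_obs}) and \code{boundary} flag.
#' @export
fit_hydrotime <- function(percentiles, theta_range = c(0.1, 500),
                          psi_ref = NULL, n_grid = 40) {
  pct <- as.data.frame(percentiles)
  temp <- unique(pct$temperature)
  if (length(temp) != 1) {
    abort_data("fit_hydrotime expects percentiles at a single temperature")
  }
  use <- pct[is.finite(pct$t_g) & pct$g > 0 & pct$g < 1, , drop = FALSE]
  if (length(unique(use$water_potential)) < 2) {
    abort_data("hydrotime fit needs germination at >= 2 water potentials")
  }
  if (nrow(use) < 4) {
    abort_data("hydrotime fit needs >= 4 usable (g, psi, t(g)) points")
  }
  y <- stats::qnorm(use$g)
  objective <- function(lth) {
    x <- use$water_potential - exp(lth) / use$t_g
    linreg(x, y)$r_squared
  }
  sr <- search_theta(objective, theta_range[1], theta_range[2], n_grid)
  theta <- exp(sr$log_theta)
  x <- use$water_potential - theta / use$t_g
  reg <- linreg(x, y)
  if (!is.finite(reg$slope) || reg$slope <= 0) {
    abort_convergence("non-positive probit slope: sigma_psib not identifiable")
  }
  psi_b50 <- -reg$intercept / reg$slope
  sigma <- 1 / reg$slope
  psi_ref <- psi_ref %||% max(use$water_potential)
  obs_rows <- pct[pct$water_potential == psi_ref, , drop = FALSE]
  observed_G <- if (nrow(obs_rows) > 0) {
    100 * obs_rows$final_fraction[1]
  } else NA_real_
  g_hat <- stats::pnorm(reg$intercept + reg$slope * x)
  rmse <- sqrt(mean((100 * use$g - 100 * g_hat)^2))
  structure(class = "hydrotime_fit", list(
    temperature = temp,
    theta_H = theta,
    psi_b50 = psi_b50,
    sigma_psib = sigma,
    psi_ref = psi_ref,
    predicted_G = 100 * stats::pnorm((psi_ref - psi_b50) / sigma),
    observed_G = observed_G,
    boundary = sr$boundary,
    diagnostics = list(r_squared = reg$r_squared, rmse = rmse,
                       n_obs = nrow(use))))
}

#' @export
print.hydrotime_fit <- function(x, ...) {
  cat("Hydrotime fit at", x$temperature, "degC\n")
  cat(sprintf("  theta_H = %.3f MPa h, psi_b50 = %.3f MPa, sigma = %.3f MPa\n",
              x$theta_H, x$psi_b50, x$sigma_psib))
  cat(sprintf("  G at %g MPa: predicted %.1f%%, observed %.1f%%\n",
              x$psi_ref, x$predicted_G, x$observed_G))
  cat(sprintf("  probit R2 = %.4f, RMSE = %.2f %%G, n = %d\n",
              x$diagnostics$r_squared, x$diagnostics$rmse,
              x$diagnostics$n_obs))
  invisible(x)
}

#' Fraction of seeds able to germinate at a water potential
#'
#' Under the fitted normal distribution of base water potentials, the
#' fraction of the lot whose threshold lies below \code{psi} (and which will
#' therefore germinate eventually at that potential) is
#' Phi((psi - psi_b50)/sigma_psib).
#'
#' @param fit a \code{hydrotime_fit} (or \code{hydrothermal_fit}).
#' @param psi water potential(s) in MPa.
#' @return Germinable fraction in [0, 1].
#' @export
germinable_fraction <- function(fit, psi) {
  stopifnot(inherits(fit, c("hydrotime_fit", "hydrothermal_fit")))
  stats::pnorm((psi - fit$psi_b50) / fit$sigma_psib)
}

#' Hydrotime fits across temperatures
#'
#' Applies [fit_hydrotime()] to every temperature (within each cultivar) in
#' a percentile table; failed fits are reported with \code{NA} parameters
#' and the failure message.
#'
#' @inheritParams fit_hydrotime
#' @return Data frame with one row per cultivar x temperature:
#'   \code{theta_H}, \code{psi_b50}, \code{sigma_psib}, \code{predicted_G},
#'   \code{observed_G}, \code{r_squared}, \code{rmse}, \code{n_obs},
#'   \code{note}.
#' @export
hydrotime_table <- function(percentiles, theta_range = c(0.1, 500),
                            psi_ref = NULL, n_grid = 40) {
  pct <- as.data.frame(percentiles)
  combos <- unique(pct[, c("cultivar", "temperature")])
  combos <- combos[order(combos$cultivar, combos$temperature), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- pct[pct$cultivar == combos$cultivar[i] &
                 pct$temperature == combos$temperature[i], , drop = FALSE]
    base <- data.frame(cultivar = combos$cultivar[i],
                       temperature = combos$temperature[i],
                       theta_H = NA_real_, psi_b50 = NA_real_,
                       sigma_psib = NA_real_, predicted_G = NA_real_,
                       observed_G = NA_real_, r_squared = NA_real_,
                       rmse = NA_real_, n_obs = NA_integer_, note = "",
                       stringsAsFactors = FALSE)
    fit <- tryCatch(
      withCallingHandlers(
        fit_hydrotime(sub, theta_range = theta_range, psi_ref = psi_ref,
                      n_grid = n_grid),
        seedhtt_boundary_warning = function(w) invokeRestart("muffleWarning")),
      seedhtt_error = function(e) e)
    if (inherits(fit, "hydrotime_fit")) {
      base$theta_H <- fit$theta_H
      base$psi_b50 <- fit$psi_b50
      base$sigma_psib <- fit$sigma_psib
      base$predicted_G <- fit$predicted_G
      base$observed_G <- fit$observed_G
      base$r_squared <- fit$diagnostics$r_squared
      base$rmse <- fit$diagnostics$rmse
      base$n_obs <- fit$diagnostics$n_obs
      if (fit$boundary) base$note <- "search optimum at grid edge"
    } else {
      base$note <- conditionMessage(fit)
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
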