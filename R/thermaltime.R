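# Thermal time model. At water potentials near zero and sub-optimal
# temperatures, the time t(g) for fraction g of a seed lot to germinate
# satisfies
#   theta_T(g) = (T - Tb) t(g)      i.e.   GR(g) = 1/t(g) = (T - Tb)/theta_T
# with a common base temperature Tb below which no germination occurs.
# GR(g) is linear in T, so Tb and theta_T come from a straight-line fit of
# germination rate on temperature.

#' Fit the thermal time model at one water potential
#'
#' Least-squares fit of the germination rate GR(g) = 1/t(g) against
#' temperature, GR = (T - Tb)/theta_T, across the temperatures of one water
#' potential. The linear form GR = a + b T gives Tb = -a/b and
#' theta_T = 1/b; a non-positive slope means the rate does not increase
#' with temperature and the model is not identifiable.
#'
#' Because the model has no ceiling-temperature term, supra-optimal
#' temperatures (where the rate declines again) are excluded by default:
#' only temperatures up to the one with maximal observed GR(g) enter the
#' fit.
#'
#' @param percentiles a \code{percentile_times} data frame restricted to a
#'   single water potential (and cultivar).
#' @param g the subpopulation fraction to model, 0.5 by default; must be one
#'   of the g levels present.
#' @param suboptimal_only drop temperatures above the observed rate optimum
#'   (default \code{TRUE}).
#' @param fixed_Tb optionally fix the base temperature (degC) and estimate
#'   only theta_T by regression through the origin of GR on (T - Tb).
#' @param reference_temp temperature (degC) at which the summary rate
#'   \code{GR_ref} = (T_ref - Tb)/theta_T is reported; 25 degC by default.
#' @return An object of class \code{thermal_time_fit}: a list with
#'   \code{theta_T} (degC h), \code{Tb} (degC), \code{GR_ref} (1/h),
#'   \code{reference_temp}, \code{water_potential}, \code{g},
#'   \code{temperatures_used} and \code{diagnostics} (\code{r_squared} on
#'   the rate scale, \code{rmse} in hours on back-predicted t(g),
#'   \code{n_obs}).
#' @export
fit_thermal_time <- function(percentiles, g = 0.5, suboptimal_only = TRUE,
                             fixed_Tb = NULL, reference_temp = 25) {
  pct <- as.data.frame(percentiles)
  psi <- unique(pct$water_potential)
  if (length(psi) != 1) {
    abort_data("fit_thermal_time expects percentiles at a single water potential")
  }
  rows <- pct[abs(pct$g - g) < 1e-9 & is.finite(pct$t_g), , drop = FALSE]
  if (nrow(rows) == 0) {
    abort_data(sprintf("no usable t(g) observations at g = %g", g))
  }
  rows <- rows[order(rows$temperature), , drop = FALSE]
  if (suboptimal_only) {
    imax <- which.max(rows$gr_g)
    rows <- rows[rows$temperature <= rows$temperature[imax], , drop = FALSE]
  }
  if (nrow(rows) < 3) {
    abort_data(sprintf(
      "thermal time fit needs >= 3 usable temperatures, got %d", nrow(rows)))
  }
  T <- rows$temperature
  GR <- rows$gr_g
  if (is.null(fixed_Tb)) {
    fit <- linreg(T, GR)
    if (!is.finite(fit$slope) || fit$slope <= 0) {
      abort_convergence(
        "non-positive slope of GR on temperature: Tb/theta_T not identifiable")
    }
    Tb <- -fit$intercept / fit$slope
    theta <- 1 / fit$slope
    r2 <- fit$r_squared
  } else {
    Tb <- fixed_Tb
    x <- T - Tb
    b <- sum(GR * x) / sum(x^2)
    if (!is.finite(b) || b <= 0) {
      abort_convergence("non-positive rate slope with fixed Tb")
    }
    theta <- 1 / b
    ss_res <- sum((GR - x / theta)^2)
    ss_tot <- sum((GR - mean(GR))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  }
  above <- T > Tb
  t_pred <- ifelse(above, theta / (T - Tb), NA_real_)
  rmse_t <- sqrt(mean((t_pred[above] - rows$t_g[above])^2))
  structure(class = "thermal_time_fit", list(
    water_potential = psi,
    g = g,
    theta_T = theta,
    Tb = Tb,
    GR_ref = (reference_temp - Tb) / theta,
    reference_temp = reference_temp,
    fixed_Tb = !is.null(fixed_Tb),
    temperatures_used = T,
    diagnostics = list(r_squared = r2, rmse = rmse_t, n_obs = nrow(rows))))
}

#' @export
print.thermal_time_fit <- function(x, ...) {
  cat("Thermal time fit (g =", x$g, ") at", x$water_potential, "MPa\n")
  cat(sprintf("  theta_T = %.1f degC h,  Tb = %.2f degC%s\n", x$theta_T,
              x$Tb, if (x$fixed_Tb) " (fixed)" else ""))
  cat(sprintf("  GR(g) at %g degC = %.5f 1/h\n", x$reference_temp, x$GR_ref))
  cat(sprintf("  R2 = %.3f (rate scale), RMSE = %.2f h, n = %d\n",
              x$diagnostics$r_squared, x$diagnostics$rmse,
              x$diagnostics$n_obs))
  invisible(x)
}

#' Predicted time to fraction g from a thermal time fit
#'
#' Inverts the fitted model: t(g) = theta_T / (T - Tb). At or below the
#' base temperature the model predicts no germination and \code{NA} is
#' returned (with a warning).
#'
#' @param fit a \code{thermal_time_fit}.
#' @param temperature temperature(s) in degC.
#' @return Predicted hours to reach the fitted fraction; \code{NA} where
#'   \code{temperature <= Tb}.
#' @export
predict_germination_time <- function(fit, temperature) {
  stopifnot(inherits(fit, "thermal_time_fit"))
  out <- ifelse(temperature > fit$Tb,
                fit$theta_T / (temperature - fit$Tb), NA_real_)
  if (any(is.na(out))) {
    warning("temperature at or below Tb: no germination predicted")
  }
  out
}

#' Thermal time fits across water potentials
#'
#' Convenience wrapper applying [fit_thermal_time()] to every water
#' potential (within each cultivar) present in a percentile table, returning
#' one summary row per fit. Water potentials where the fit fails (too few
#' usable temperatures, non-identifiable slope) are reported with \code{NA}
#' parameters and the failure message.
#'
#' @inheritParams fit_thermal_time
#' @return Data frame with columns \code{cultivar}, \code{water_potential},
#'   \code{theta_T}, \code{Tb}, \code{rmse}, \code{r_squared},
#'   \code{GR_ref}, \code{n_obs} and \code{note}.
#' @export
thermal_time_table <- function(percentiles, g = 0.5, suboptimal_only = TRUE,
                               fixed_Tb = NULL, reference_temp = 25) {
  pct <- as.data.frame(percentiles)
  combos <- unique(pct[, c("cultivar", "water_potential")])
  combos <- combos[order(combos$cultivar, -combos$water_potential), ,
                   drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- pct[pct$cultivar == combos$cultivar[i] &
                 pct$water_potential == combos$water_potential[i], ,
               drop = FALSE]
    base <- data.frame(cultivar = combos$cultivar[i],
                       water_potential = combos$water_potential[i],
                       theta_T = NA_real_, Tb = NA_real_, rmse = NA_real_,
                       r_squared = NA_real_, GR_ref = NA_real_,
                       n_obs = NA_integer_, note = "",
                       stringsAsFactors = FALSE)
    fit <- tryCatch(
      fit_thermal_time(sub, g = g, suboptimal_only = suboptimal_only,
                       fixed_Tb = fixed_Tb, reference_temp = reference_temp),
      seedhtt_error = function(e) e)
    if (inherits(fit, "thermal_time_fit")) {
      base$theta_T <- fit$theta_T
      base$Tb <- fit$Tb
      base$rmse <- fit$diagnostics$rmse
      base$r_squared <- fit$diagnostics$r_squared
      base$GR_ref <- fit$GR_ref
      base$n_obs <- fit$diagnostics$n_obs
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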