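# Exact-quantile data generators: percentile tables computed in closed form
# from the threshold models, independent of the package's own percentile
# extraction, for use as noiseless fitting oracles.

percentile_row <- function(cultivar, temperature, psi, g, t_g, final_frac,
                           n_total = 200) {
  data.frame(cultivar = cultivar, temperature = temperature,
             water_potential = psi, g = g, t_g = t_g, gr_g = 1 / t_g,
             final_fraction = final_frac, n_total = n_total,
             stringsAsFactors = FALSE)
}

# Thermal time: t(g) = theta_T / (T - Tb) at one water potential.
exact_tt_percentiles <- function(theta_T, Tb, temps, psi = 0, g = 0.5) {
  t_g <- ifelse(temps > Tb, theta_T / (temps - Tb), NA_real_)
  percentile_row("oracle", temps, psi, g, t_g, final_frac = 1)
}

# Hydrotime at one temperature: seed fraction g has base water potential
# psi_b50 + sigma * qnorm(g) and germinates at theta_H/(psi - psi_b(g)).
exact_ht_percentiles <- function(theta_H, psi_b50, sigma, psis,
                                 temperature = 20,
                                 g_levels = seq(0.1, 0.9, by = 0.1)) {
  do.call(rbind, lapply(psis, function(p) {
    psi_bg <- psi_b50 + sigma * stats::qnorm(g_levels)
    t_g <- ifelse(p > psi_bg, theta_H / (p - psi_bg), NA_real_)
    percentile_row("oracle", temperature, p, g_levels, t_g,
                   final_frac = stats::pnorm((p - psi_b50) / sigma))
  }))
}

# Hydrothermal time over a T x psi grid.
exact_htt_percentiles <- function(theta_HT, Tb, psi_b50, sigma, temps, psis,
                                  g_levels = seq(0.1, 0.9, by = 0.1)) {
  do.call(rbind, lapply(temps, function(T) {
    do.call(rbind, lapply(psis, function(p) {
      psi_bg <- psi_b50 + sigma * stats::qnorm(g_levels)
      t_g <- ifelse(p > psi_bg & T > Tb,
                    theta_HT / ((p - psi_bg) * (T - Tb)), NA_real_)
      percentile_row("oracle", T, p, g_levels, t_g,
                     final_frac = stats::pnorm((p - psi_b50) / sigma))
    }))
  }))
}

# A small hand-enterable counts table: one dish scored five times.
make_counts <- function(cum, times = seq(8, by = 8, length.out = length(cum)),
                        cultivar = "cv", temperature = 25,
                        water_potential = 0, replicate = 1, n_sown = 50) {
  data.frame(cultivar = cultivar, temperature = temperature,
             water_potential = water_potential, replicate = replicate,
             n_sown = n_sown, time = times, cum_germinated = cum,
             stringsAsFactors = FALSE)
}

# Gaussian blobs for clustering checks: k well-separated centres in p dims.
make_blobs <- function(centres, n_per, sd = 0.05) {
  X <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    matrix(stats::rnorm(n_per * ncol(centres), mean = 0, sd = sd),
           n_per, ncol(centres)) +
      matrix(centres[i, ], n_per, ncol(centres), byrow = TRUE)
  }))
  rownames(X) <- paste0("r", seq_len(nrow(X)))
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  list(x = as.data.frame(X),
       truth = rep(seq_len(nrow(centres)), each = n_per))
}
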