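# Internal helpers shared across the fitting modules.

# Condition constructors. The CLI maps these classes to exit codes, so every
# user-facing validation failure should go through one of them.
abort_schema <- function(msg) {
  stop(structure(class = c("seedhtt_schema_error", "seedhtt_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

abort_data <- function(msg) {
  stop(structure(class = c("seedhtt_data_error", "seedhtt_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

abort_convergence <- function(msg) {
  stop(structure(class = c("seedhtt_convergence_error", "seedhtt_error",
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}

warn_boundary <- function(msg) {
  warning(structure(class = c("seedhtt_boundary_warning", "warning",
                              "condition"),
                    list(message = msg, call = NULL)))
}

# Simple linear regression y = a + b x by explicit sums; called thousands of
# times inside the grid searches, so it avoids the lm() overhead.
linreg <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  b <- sxy / sxx
  a <- my - b * mx
  r2 <- if (syy > 0) (sxy * sxy) / (sxx * syy) else NA_real_
  list(intercept = a, slope = b, r_squared = r2, n = n)
}

treatment_key <- function(df) {
  paste(df$cultivar, df$temperature, df$water_potential, sep = "\r")
}

dish_key <- function(df) {
  paste(df$cultivar, df$temperature, df$water_potential, df$replicate,
        sep = "\r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
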