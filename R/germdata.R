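#' Read germination count time courses from delimited text
#'
#' Reads a tabular file with one row per cultivar x temperature x water
#' potential x replicate x scoring time, carrying the cumulative number of
#' germinated seeds and the number of seeds sown. This is the raw observable
#' of a germination trial scored at fixed intervals (a seed counts as
#' germinated once the radicle has protruded).
#'
#' The file must contain the columns \code{cultivar}, \code{temperature_C},
#' \code{water_potential_MPa}, \code{replicate}, \code{n_sown},
#' \code{time_h} and \code{cum_germinated}. Rows are sorted by time within
#' each dish and validated: times must be positive and strictly increasing,
#' cumulative counts non-decreasing and within \code{[0, n_sown]}, water
#' potentials non-positive.
#'
#' @param path path to a delimited text file (UTF-8).
#' @param delim field delimiter, comma by default.
#' @return A data frame of class \code{germination_counts} with columns
#'   \code{cultivar}, \code{temperature} (degC), \code{water_potential}
#'   (MPa), \code{replicate}, \code{n_sown}, \code{time} (hours since
#'   imbibition) and \code{cum_germinated}.
#' @seealso [simulate_trial()] to generate data in this schema,
#'   [percentile_times()] for the downstream percentile extraction.
#' @export
read_germination_counts <- function(path, delim = ",") {
  if (!file.exists(path)) abort_data(sprintf("file not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           fileEncoding = "UTF-8")
  required <- c("cultivar", "temperature_C", "water_potential_MPa",
                "replicate", "n_sown", "time_h", "cum_germinated")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_schema(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- data.frame(cultivar = as.character(raw$cultivar),
                   temperature = as.numeric(raw$temperature_C),
                   water_potential = as.numeric(raw$water_potential_MPa),
                   replicate = raw$replicate,
                   n_sown = as.numeric(raw$n_sown),
                   time = as.numeric(raw$time_h),
                   cum_germinated = as.numeric(raw$cum_germinated),
                   stringsAsFactors = FALSE)
  validate_counts(df)
}

#' Write germination counts in the canonical file schema
#'
#' Inverse of [read_germination_counts()]; the written file round-trips to
#' identical counts.
#'
#' @param counts a \code{germination_counts} data frame.
#' @param path output path.
#' @param delim field delimiter.
#' @return \code{path}, invisibly.
#' @export
write_germination_counts <- function(counts, path, delim = ",") {
  out <- data.frame(cultivar = counts$cultivar,
                    temperature_C = counts$temperature,
                    water_potential_MPa = counts$water_potential,
                    replicate = counts$replicate,
                    n_sown = counts$n_sown,
                    time_h = counts$time,
                    cum_germinated = counts$cum_germinated)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a germination counts data frame
#'
#' Checks the invariants of a cumulative germination time course: positive,
#' strictly increasing scoring times within each dish; non-decreasing
#' cumulative counts bounded by the number of seeds sown; non-positive water
#' potentials. Returns the data sorted by dish and time.
#'
#' @param counts data frame with the canonical columns (see
#'   [read_germination_counts()]).
#' @return The validated, sorted data frame with class
#'   \code{germination_counts}.
#' @export
validate_counts <- function(counts) {
  required <- c("cultivar", "temperature", "water_potential", "replicate",
                "n_sown", "time", "cum_germinated")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort_schema(sprintf("missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (any(!is.finite(df$temperature))) abort_data("non-finite temperature")
  if (any(df$water_potential > 0)) {
    abort_data("water_potential must be <= 0 MPa")
  }
  if (any(df$time <= 0)) abort_data("scoring times must be > 0 h")
  if (any(df$n_sown <= 0)) abort_data("n_sown must be positive")
  if (any(df$cum_germinated < 0 | df$cum_germinated > df$n_sown)) {
    abort_data("cum_germinated must lie in [0, n_sown]")
  }
  key <- dish_key(df)
  df <- df[order(key, df$time), , drop = FALSE]
  key <- dish_key(df)
  for (k in unique(key)) {
    idx <- which(key == k)
    tt <- df$time[idx]
    cc <- df$cum_germinated[idx]
    if (any(diff(tt) <= 0)) {
      abort_data(sprintf("duplicated or non-increasing scoring time in dish %s",
                         gsub("\r", "/", k)))
    }
    bad <- which(diff(cc) < 0)
    if (length(bad) > 0) {
      abort_data(sprintf(
        "decreasing cumulative count in dish %s at time %g h (%g after %g)",
        gsub("\r", "/", k), tt[bad[1] + 1], cc[bad[1] + 1], cc[bad[1]]))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("germination_counts", "data.frame")
  df
}

#' Drop the trailing plateau of each germination time course
#'
#' Once a dish shows no further increase in the cumulative count, the later
#' observations carry no information about germination timing and are
#' removed before model fitting: each course is cut after the first time its
#' maximum count is reached. A course with no germination at all is reduced
#' to its final observation and flagged.
#'
#' The operation is idempotent.
#'
#' @param counts a validated \code{germination_counts} data frame.
#' @return The truncated data frame. Courses with zero germination are
#'   listed in the \code{"non_germinating"} attribute (one row per dish).
#' @export
truncate_plateau <- function(counts) {
  df <- validate_counts(counts)
  key <- dish_key(df)
  keep <- logical(nrow(df))
  nong <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    cc <- df$cum_germinated[idx]
    if (max(cc) == 0) {
      keep[idx[length(idx)]] <- TRUE
      nong[[length(nong) + 1]] <- df[idx[1], c("cultivar", "temperature",
                                               "water_potential", "replicate")]
    } else {
      last <- which(cc == max(cc))[1]
      keep[idx[seq_len(last)]] <- TRUE
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("germination_counts", "data.frame")
  attr(out, "non_germinating") <-
    if (length(nong) > 0) do.call(rbind, nong) else NULL
  out
}

#' Final germination percentage
#'
#' The percentage of sown seeds that had germinated by the end of the test,
#' per dish or pooled over replicates of each treatment. Pooling is
#' count-weighted (total germinated over total sown), which differs from the
#' mean of replicate percentages when dishes hold different numbers of
#' seeds.
#'
#' @param counts a \code{germination_counts} data frame.
#' @param by_replicate if \code{TRUE}, one row per dish; otherwise one row
#'   per treatment, pooled over replicates.
#' @return Data frame with the treatment columns and \code{G} (percent).
#' @export
final_germination <- function(counts, by_replicate = FALSE) {
  df <- validate_counts(counts)
  key <- if (by_replicate) dish_key(df) else treatment_key(df)
  rows <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    sub <- df[idx, , drop = FALSE]
    dk <- dish_key(sub)
    germ <- vapply(unique(dk),
                   function(d) max(sub$cum_germinated[dk == d]), 0)
    sown <- vapply(unique(dk), function(d) sub$n_sown[dk == d][1], 0)
    out <- sub[1, c("cultivar", "temperature", "water_potential")]
    if (by_replicate) out$replicate <- sub$replicate[1]
    out$n_sown <- sum(sown)
    out$germinated <- sum(germ)
    out$G <- 100 * sum(germ) / sum(sown)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pool replicate dishes of one treatment onto the union of their scoring
# times. Cumulative counts are step functions, so a dish truncated earlier
# (plateau removed) contributes its plateau value at later times.
pool_courses <- function(sub) {
  dk <- dish_key(sub)
  times <- sort(unique(sub$time))
  total <- numeric(length(times))
  n_sown <- 0
  for (d in unique(dk)) {
    rows <- sub[dk == d, , drop = FALSE]
    n_sown <- n_sown + rows$n_sown[1]
    f <- stats::stepfun(rows$time, c(0, rows$cum_germinated), right = FALSE)
    total <- total + f(times)
  }
  list(time = times, cum = total, n_sown = n_sown)
}

#' Time for a cumulative curve to reach a fraction
#'
#' Linear interpolation of a cumulative germination-fraction curve to find
#' t(g), the time at which fraction \code{g} of the population has
#' germinated. The curve is anchored at the origin (no seed has germinated
#' at imbibition), and is never extrapolated beyond the last scoring time:
#' if the curve never reaches \code{g}, \code{NA} is returned.
#'
#' @param time scoring times (hours, increasing).
#' @param fraction cumulative germinated fractions aligned with \code{time}.
#' @param g target fraction, strictly between 0 and 1.
#' @return t(g) in hours, or \code{NA_real_} when the fraction is never
#'   reached.
#' @export
time_to_fraction <- function(time, fraction, g) {
  if (!is.numeric(g) || length(g) != 1 || is.na(g) || g <= 0 || g >= 1) {
    abort_data("g must be a single fraction strictly inside (0, 1)")
  }
  tt <- c(0, time)
  ff <- c(0, fraction)
  if (max(ff) < g) return(NA_real_)
  i <- which(ff >= g)[1]
  if (ff[i] == g) return(tt[i])
  # bracketing points (i-1, i); ff[i-1] < g < ff[i]
  tt[i - 1] + (g - ff[i - 1]) * (tt[i] - tt[i - 1]) / (ff[i] - ff[i - 1])
}

#' Percentile germination times t(g) per treatment
#'
#' Pools the replicate dishes of each cultivar x temperature x water
#' potential treatment, converts the pooled cumulative counts to fractions,
#' and interpolates the times t(g) at which each requested subpopulation
#' fraction g germinated, together with the germination rates
#' GR(g) = 1/t(g). These percentile times are the inputs of all three
#' threshold-model fitters.
#'
#' Fractions are computed relative to the number of seeds sown by default,
#' matching a probit analysis that regresses population fractions against
#' base-water-potential quantiles of the whole seed lot; \code{basis =
#' "final"} rescales by the final germinated count instead, for sensitivity
#' checks. Treatments whose pooled germinated count is below
#' \code{min_germinated} (default 1, i.e. only complete failures) are
#' excluded and recorded in the \code{"excluded"} attribute.
#'
#' @param counts a \code{germination_counts} data frame.
#' @param g_levels fractions in (0,1) at which to interpolate; deciles by
#'   default.
#' @param basis \code{"sown"} (default) or \code{"final"}.
#' @param min_germinated minimum pooled germinated count for a treatment to
#'   be retained.
#' @return Data frame of class \code{percentile_times} with one row per
#'   treatment x g level: columns \code{cultivar}, \code{temperature},
#'   \code{water_potential}, \code{g}, \code{t_g} (hours; \code{NA} when the
#'   curve never reaches g), \code{gr_g} (= 1/t(g)), \code{final_fraction}
#'   (pooled final fraction of sown) and \code{n_total} (pooled seeds sown).
#' @export
percentile_times <- function(counts, g_levels = seq(0.1, 0.9, by = 0.1),
                             basis = c("sown", "final"),
                             min_germinated = 1) {
  basis <- match.arg(basis)
  if (any(g_levels <= 0 | g_levels >= 1)) {
    abort_data("g_levels must lie strictly inside (0, 1)")
  }
  g_levels <- sort(unique(g_levels))
  df <- validate_counts(counts)
  key <- treatment_key(df)
  rows <- list()
  excluded <- list()
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    pooled <- pool_courses(sub)
    germinated <- max(pooled$cum)
    if (germinated < min_germinated) {
      excluded[[length(excluded) + 1]] <-
        data.frame(sub[1, c("cultivar", "temperature", "water_potential")],
                   germinated = germinated, row.names = NULL)
      next
    }
    denom <- if (basis == "sown") pooled$n_sown else germinated
    frac <- pooled$cum / denom
    t_g <- vapply(g_levels, function(g)
      time_to_fraction(pooled$time, frac, g), 0)
    rows[[length(rows) + 1]] <- data.frame(
      cultivar = sub$cultivar[1],
      temperature = sub$temperature[1],
      water_potential = sub$water_potential[1],
      g = g_levels,
      t_g = t_g,
      gr_g = 1 / t_g,
      final_fraction = germinated / pooled$n_sown,
      n_total = pooled$n_sown,
      row.names = NULL)
  }
  if (length(rows) == 0) abort_data("no treatment has enough germination")
  out <- do.call(rbind, rows)
  class(out) <- c("percentile_times", "data.frame")
  attr(out, "g_levels") <- g_levels
  attr(out, "basis") <- basis
  attr(out, "min_germinated") <- min_germinated
  attr(out, "excluded") <-
    if (length(excluded) > 0) do.call(rbind, excluded) else NULL
  out
}
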