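# Orchestration: read or simulate a trial, apply the exclusion/truncation
# rules, extract percentile times, fit the three threshold models, and
# (optionally) run the multivariate stage, writing one CSV per stage plus a
# JSON manifest that records every decision needed to reproduce the run.

pipeline_keys <- c("seed", "input", "simulate", "percentiles",
                   "thermal_time", "hydrotime", "htt", "pca", "delim")

#' Run the full germination-modelling pipeline
#'
#' Stages, in order: load counts (from \code{input}) or generate them (from
#' \code{simulate}); truncate post-plateau observations; extract percentile
#' germination times (excluding zero-germination treatments); thermal time
#' fits per water potential; hydrotime fits per temperature; hydrothermal
#' time fit per cultivar; optional PCA + HCPC of a trait table. Each stage
#' writes a CSV into \code{out_dir}; a \code{manifest.json} records the
#' configuration, file checksums, exclusions applied, parameter decisions
#' and seeds. If a stage fails, a \code{<stage>.failed} marker file is left
#' next to the partial outputs and the error is re-signalled.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized keys: \code{seed}, \code{input} (counts CSV path),
#'   \code{simulate} (arguments of [trial_config()]), \code{percentiles},
#'   \code{thermal_time}, \code{hydrotime}, \code{htt} (stage options),
#'   \code{pca} (\code{traits} CSV path, \code{active},
#'   \code{supplementary}, \code{clusters}), \code{delim}. Unknown keys are
#'   a schema error.
#' @param out_dir output directory, created if needed.
#' @return \code{out_dir}, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_schema("config must be a YAML file or a list")
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0) {
    abort_schema(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (is.null(config$input) && is.null(config$simulate)) {
    abort_schema("config needs either 'input' or 'simulate'")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  delim <- config$delim %||% ","
  manifest <- list(command = "run_pipeline",
                   package_version =
                     as.character(utils::packageVersion("seedhtt")),
                   seed = seed, config = config,
                   inputs = list(), decisions = list(), exclusions = list())
  if (!is.null(cfg_path)) {
    manifest$config_file <- cfg_path
    manifest$config_checksum <- unname(tools::md5sum(cfg_path))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0(name, ".failed")))
      writeLines(conditionMessage(e),
                 file.path(out_dir, paste0(name, ".failed")))
      stop(e)
    })
  }

  counts <- stage("counts", {
    if (!is.null(config$input)) {
      manifest$inputs$counts <- list(
        path = config$input,
        checksum = unname(tools::md5sum(config$input)))
      read_germination_counts(config$input, delim = delim)
    } else {
      sim_args <- config$simulate
      if (is.null(sim_args$rng_seed)) sim_args$rng_seed <- seed
      cfg <- do.call(trial_config, sim_args)
      manifest$decisions$simulate <- unclass(cfg)
      tr <- simulate_trial(cfg)
      write_germination_counts(tr, file.path(out_dir, "counts.csv"))
      tr
    }
  })
  message(sprintf("[seedhtt] %d count rows loaded", nrow(counts)))

  pct <- stage("percentiles", {
    trimmed <- truncate_plateau(counts)
    popt <- config$percentiles %||% list()
    p <- percentile_times(
      trimmed,
      g_levels = unlist(popt$g_levels %||% seq(0.1, 0.9, by = 0.1)),
      basis = popt$basis %||% "sown",
      min_germinated = popt$min_germinated %||% 1)
    manifest$decisions$percentiles <- list(
      g_levels = attr(p, "g_levels"), basis = attr(p, "basis"),
      min_germinated = attr(p, "min_germinated"))
    excl <- attr(p, "excluded")
    manifest$exclusions$zero_germination_treatments <-
      if (is.null(excl)) list() else excl
    utils::write.csv(as.data.frame(p),
                     file.path(out_dir, "percentile_times.csv"),
                     row.names = FALSE)
    p
  })
  message(sprintf("[seedhtt] percentile times for %d treatment(s)",
                  nrow(unique(pct[, c("cultivar", "temperature",
                                      "water_potential")]))))

  stage("thermal_time", {
    topt <- config$thermal_time %||% list()
    tt <- thermal_time_table(
      pct, g = topt$g %||% 0.5,
      suboptimal_only = topt$suboptimal_only %||% TRUE,
      fixed_Tb = topt$fixed_Tb,
      reference_temp = topt$reference_temp %||% 25)
    manifest$decisions$thermal_time <- list(
      g = topt$g %||% 0.5, suboptimal_only = topt$suboptimal_only %||% TRUE,
      reference_temp = topt$reference_temp %||% 25,
      rmse_units = "hours, on back-predicted t(g)")
    utils::write.csv(tt, file.path(out_dir, "thermal_time.csv"),
                     row.names = FALSE)
  })

  stage("hydrotime", {
    hopt <- config$hydrotime %||% list()
    ht <- hydrotime_table(
      pct, theta_range = unlist(hopt$theta_range %||% c(0.1, 500)),
      psi_ref = hopt$psi_ref)
    manifest$decisions$hydrotime <- list(
      theta_range = unlist(hopt$theta_range %||% c(0.1, 500)),
      psi_ref = hopt$psi_ref %||% "highest water potential with data")
    utils::write.csv(ht, file.path(out_dir, "hydrotime.csv"),
                     row.names = FALSE)
  })

  stage("hydrothermal_time", {
    hopt <- config$htt %||% list()
    n_boot <- hopt$n_boot %||% 200
    rows <- lapply(unique(pct$cultivar), function(cv) {
      sub <- pct[pct$cultivar == cv, , drop = FALSE]
      for (a in c("g_levels", "basis", "min_germinated")) {
        attr(sub, a) <- attr(pct, a)
      }
      fit <- suppressWarnings(fit_htt(
        sub, fixed_Tb = hopt$fixed_Tb,
        temp_window = unlist(hopt$temp_window),
        theta_range = unlist(hopt$theta_range %||% c(1, 1e5)),
        counts = if (n_boot > 0) {
          counts[counts$cultivar == cv, , drop = FALSE]
        },
        n_boot = n_boot, boot_seed = seed))
      data.frame(cultivar = cv, temp_lo = fit$temp_range_used[1],
                 temp_hi = fit$temp_range_used[2], Tb = fit$Tb,
                 psi_b50 = fit$psi_b50, sigma_psib = fit$sigma_psib,
                 r_squared = fit$diagnostics$r_squared,
                 rmse = fit$diagnostics$rmse, theta_HT = fit$theta_HT,
                 sem = fit$diagnostics$sem, stringsAsFactors = FALSE)
    })
    manifest$decisions$htt <- list(
      Tb_mode = if (is.null(hopt$fixed_Tb)) "estimated jointly" else "fixed",
      bootstrap_B = n_boot, bootstrap_seed = seed)
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "hydrothermal_time.csv"),
                     row.names = FALSE)
  })

  if (!is.null(config$pca)) {
    stage("pca", {
      popt <- config$pca
      traits <- utils::read.csv(popt$traits, row.names = 1,
                                check.names = FALSE)
      manifest$inputs$traits <- list(
        path = popt$traits, checksum = unname(tools::md5sum(popt$traits)))
      res <- trait_pca(traits, active = unlist(popt$active),
                       supplementary = unlist(popt$supplementary))
      utils::write.csv(res$scores, file.path(out_dir, "pca_scores.csv"))
      utils::write.csv(res$loadings, file.path(out_dir, "pca_loadings.csv"))
      utils::write.csv(res$contributions,
                       file.path(out_dir, "pca_contributions.csv"))
      utils::write.csv(res$cos2, file.path(out_dir, "pca_cos2.csv"))
      if (!is.null(res$supplementary)) {
        utils::write.csv(res$supplementary$coordinates,
                         file.path(out_dir, "pca_supplementary.csv"))
      }
      k <- popt$clusters %||% 3
      cl <- hcpc(res, k = k)
      clusters <- data.frame(cultivar = names(cl), cluster = as.vector(cl))
      con <- file(file.path(out_dir, "clusters.ndjson"), "w")
      for (i in seq_len(nrow(clusters))) {
        writeLines(jsonlite::toJSON(as.list(clusters[i, ]),
                                    auto_unbox = TRUE), con)
      }
      close(con)
      manifest$decisions$pca <- list(
        standardize = TRUE, clusters = k,
        linkage = "ward.D2 on Euclidean PC-score distances")
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  message(sprintf("[seedhtt] pipeline complete: %s", out_dir))
  invisible(out_dir)
}
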