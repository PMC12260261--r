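#' Simulate a cohort to disk
#'
#' Expands the configuration into per-plan specs, generates the cohort,
#' and writes: one planned sinogram CSV per plan
#' (\code{sinogram_<plan>_plan.csv}), one measured sinogram CSV per
#' fraction (\code{sinogram_<plan>_f<k>.csv}), the session table
#' (\code{sessions.csv}) and a run manifest (\code{manifest.json}) whose
#' content fingerprints are reproducible for the same config and seed.
#'
#' @param config Cohort configuration (see
#'   \code{\link{default_cohort_config}}).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed overriding \code{config$seed} when given.
#' @param write_sinograms Write per-fraction sinogram CSVs (default TRUE);
#'   the session table alone suffices for the statistical analyses.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(config = default_cohort_config(), out_dir,
                         seed = NULL, write_sinograms = TRUE) {
  validate_cohort_config(config)
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$error_model$seed <- as.integer(seed)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_lotqa("lotqa_io_error", "cannot create output directory %s", out_dir)
  specs <- cohort_specs_from_config(config)
  cohort <- generate_cohort(specs, config$seed,
                            bin_width_ms = config$bin_width_ms,
                            gamma_model = config$gamma_model,
                            signal_noise_sd = config$signal_noise_sd)
  outputs <- character()
  if (write_sinograms) {
    for (plan in cohort$planned) {
      f <- file.path(out_dir, sprintf("sinogram_%s_plan.csv", plan$plan_id))
      write_sinogram_csv(plan, f)
      outputs <- c(outputs, f)
    }
    for (meas in cohort$measured) {
      f <- file.path(out_dir, sprintf("sinogram_%s_f%d.csv",
                                      meas$plan_id, meas$fraction_index))
      write_sinogram_csv(meas, f)
      outputs <- c(outputs, f)
    }
  }
  sess_path <- file.path(out_dir, "sessions.csv")
  write_session_csv(cohort$sessions, sess_path)
  outputs <- c(outputs, sess_path)
  manifest <- write_manifest(out_dir, config, outputs, step = "simulate")
  invisible(manifest)
}

#' Analyze a simulated cohort directory
#'
#' Reads \code{sessions.csv} and writes the full analysis set:
#' \code{summary_site.csv} and \code{summary_plan.csv} (group, n,
#' mean, SD, IQR, worst plan, greatest-variation plan),
#' \code{outliers.csv} (IQR-fence outlier sessions per site),
#' \code{correlations.csv} (Spearman rho, strength class and p per site
#' and overall, attainment vs each gamma column),
#' \code{welch_site.csv} (site-vs-pooled Welch p-values per metric) and
#' \code{trend_flags.csv} (fractions where detector signal and attainment
#' co-decline, per plan). Outputs are byte-stable for identical input.
#'
#' @param in_dir Directory holding \code{sessions.csv}.
#' @param options Analysis options; defaults from
#'   \code{default_cohort_config()$analysis}.
#' @return Named list of the result data.frames, invisibly.
#' @export
run_analyze <- function(in_dir, options = default_cohort_config()$analysis) {
  sess_path <- file.path(in_dir, "sessions.csv")
  if (!file.exists(sess_path))
    stop_lotqa("lotqa_io_error",
               "no sessions.csv in %s; run the simulation step first", in_dir)
  records <- read_session_csv(sess_path)
  fm <- options$fence_multiplier

  site_sum <- summarize_with_plan_extremes(records, "site", options)
  all_sum <- summarize_with_plan_extremes(records, "all", options)
  summary_site <- rbind(all_sum, site_sum)
  plan_sum <- summarize_sessions(records, "plan",
                                 aggregation = options$aggregation,
                                 fence_multiplier = fm)
  summary_plan <- plan_sum[, c("group_label", "n", "mean", "sd", "iqr")]

  out_rows <- list()
  raw_site <- summarize_sessions(records, "site",
                                 aggregation = options$aggregation,
                                 fence_multiplier = fm)
  for (i in seq_len(nrow(raw_site))) {
    o <- raw_site$outliers[[i]]
    if (nrow(o))
      out_rows[[length(out_rows) + 1L]] <-
        cbind(site = raw_site$group_label[i], o)
  }
  outliers <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(site = character(), plan_id = character(),
               fraction = integer(), eta_percent = numeric())

  correlations <- correlate_gamma(records)
  welch_site <- site_vs_all_tests(records,
                                  metrics = c("eta_percent", "gamma_delta4",
                                              "gamma_film_cor",
                                              "gamma_film_sag"))

  trend_rows <- list()
  for (pid in sort(unique(records$plan_id))) {
    r <- records[records$plan_id == pid, , drop = FALSE]
    if (sum(is.finite(r$detector_signal) & is.finite(r$eta_percent)) < 3) next
    fl <- fraction_trend(r, options$signal_threshold_z, options$eta_threshold_z)
    if (length(fl))
      trend_rows[[length(trend_rows) + 1L]] <-
        data.frame(plan_id = pid, fraction = fl, stringsAsFactors = FALSE)
  }
  trend_flags <- if (length(trend_rows)) do.call(rbind, trend_rows) else
    data.frame(plan_id = character(), fraction = integer())

  results <- list(summary_site = summary_site, summary_plan = summary_plan,
                  outliers = outliers, correlations = correlations,
                  welch_site = welch_site, trend_flags = trend_flags)
  for (nm in names(results))
    write_result_csv(results[[nm]], file.path(in_dir, paste0(nm, ".csv")))
  invisible(results)
}

# Site/all summary augmented with the worst plan (lowest per-plan mean) and
# the greatest-variation plan (highest per-plan SD) inside each group.
summarize_with_plan_extremes <- function(records, group_by, options) {
  s <- summarize_sessions(records, group_by,
                          aggregation = options$aggregation,
                          fence_multiplier = options$fence_multiplier)
  key <- if (group_by == "all") rep("all", nrow(records)) else records$site
  extremes <- lapply(s$group_label, function(lab) {
    g <- records[key == lab, , drop = FALSE]
    pm <- tapply(g$eta_percent, g$plan_id, mean)
    ps <- tapply(g$eta_percent, g$plan_id, function(v)
      if (length(v) > 1) stats::sd(v) else 0)
    worst <- names(pm)[which.min(pm)]
    most_var <- names(ps)[which.max(ps)]
    data.frame(worst_plan = worst, worst_plan_mean = unname(pm[worst]),
               worst_plan_sd = unname(ps[worst]),
               most_variable_plan = most_var,
               most_variable_plan_mean = unname(pm[most_var]),
               most_variable_plan_sd = unname(ps[most_var]),
               stringsAsFactors = FALSE)
  })
  cbind(s[, c("group_label", "n", "mean", "sd", "iqr")],
        do.call(rbind, extremes))
}

# Spearman correlation of attainment vs each gamma column, overall and per
# site, with the five-level strength labels.
correlate_gamma <- function(records) {
  gammas <- c("gamma_delta4", "gamma_film_cor", "gamma_film_sag")
  groups <- c("all", sort(unique(records$site)))
  rows <- list()
  for (g in groups) {
    r <- if (g == "all") records else records[records$site == g, , drop = FALSE]
    for (gc in gammas) {
      ok <- is.finite(r$eta_percent) & is.finite(r[[gc]])
      if (sum(ok) < 3) next
      res <- tryCatch(spearman_cor(r$eta_percent[ok], r[[gc]][ok]),
                      lotqa_undefined_statistic_error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, metric = gc, n = res$n, rho = res$rho,
                   strength = res$strength, p_value = res$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(), metric = character(),
                      n = integer(), rho = numeric(), strength = character(),
                      p_value = numeric())
  out
}

# Fixed-format CSV writer: percents and statistics to stable decimals so
# repeated runs are byte-identical.
write_result_csv <- function(df, path) {
  fmt <- function(v) {
    if (is.numeric(v)) {
      ifelse(is.na(v), "", ifelse(v == round(v) & abs(v) < 1e15,
                                  sprintf("%d", as.integer(round(v))),
                                  sprintf("%.6f", v)))
    } else as.character(v)
  }
  cols <- lapply(df, fmt)
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

# Emit the run manifest: config hash, seed, package version, outputs with
# content fingerprints, timestamp.
write_manifest <- function(out_dir, config, outputs, step) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "lotqa",
    version = as.character(utils::packageVersion("lotqa")),
    step = step,
    seed = config$seed,
    config_hash = fnv1a_hash(as.character(cfg_json)),
    outputs = lapply(outputs, function(f)
      list(path = basename(f),
           hash = fnv1a_hash(paste(readLines(f), collapse = "\n")))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
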