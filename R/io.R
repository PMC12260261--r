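#' Write a sinogram to long-format CSV
#'
#' Sparse long format: one row per nonzero entry, columns
#' \code{plan_id, fraction, projection, leaf, lot_ms} with 0-based
#' projection and leaf indices and \code{fraction = 0} for a planned
#' sinogram. Matrix dimensions, projection duration and (for measured
#' sinograms) sensor resolution and detector signal are carried in
#' \code{#}-prefixed metadata lines before the header so an all-zero tail
#' of the matrix survives the round trip. Output is byte-stable for
#' identical input.
#'
#' @param sinogram A \code{planned_sinogram} or \code{measured_sinogram}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sinogram_csv <- function(sinogram, path) {
  planned <- inherits(sinogram, "planned_sinogram")
  if (!planned && !inherits(sinogram, "measured_sinogram"))
    stop_lotqa("lotqa_parameter_error", "not a sinogram object")
  lot <- sinogram$lot_ms
  idx <- which(lot > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  frac <- if (planned) 0L else sinogram$fraction_index
  meta <- c(
    sprintf("# n_projections=%d", nrow(lot)),
    sprintf("# n_leaves=%d", ncol(lot)),
    sprintf("# projection_duration_ms=%.17g", sinogram$projection_duration_ms),
    sprintf("# site=%s", sinogram$site)
  )
  if (!planned) {
    meta <- c(meta,
              sprintf("# sensor_resolution_ms=%.17g", sinogram$sensor_resolution_ms),
              sprintf("# detector_signal=%.17g", sinogram$detector_signal))
  }
  body <- sprintf("%s,%d,%d,%d,%.17g",
                  sinogram$plan_id, frac,
                  idx[, 1] - 1L, idx[, 2] - 1L, lot[idx])
  writeLines(c(meta, "plan_id,fraction,projection,leaf,lot_ms", body), path)
  invisible(path)
}

read_sinogram_meta <- function(path) {
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([a-z_]+)=(.*)$", meta_lines))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Read a sinogram from long-format CSV
#'
#' Strictly parses the dialect written by \code{\link{write_sinogram_csv}}:
#' absent (projection, leaf) rows mean LOT 0, duplicate rows are an error,
#' negative LOTs and out-of-range leaf indices are validation errors.
#' \code{fraction = 0} yields a \code{planned_sinogram}; any other
#' fraction a \code{measured_sinogram}. Without metadata lines the matrix
#' dimensions are inferred from the maximum indices and
#' \code{projection_duration_ms} must be supplied.
#'
#' @param path Input CSV path.
#' @param projection_duration_ms Fallback projection duration when the
#'   file carries no metadata.
#' @return A \code{planned_sinogram} or \code{measured_sinogram}.
#' @export
read_sinogram_csv <- function(path, projection_duration_ms = NULL) {
  if (!file.exists(path))
    stop_lotqa("lotqa_io_error", "no such file: %s", path)
  meta <- read_sinogram_meta(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plan_id", "fraction", "projection", "leaf", "lot_ms")
  if (!identical(sort(names(df)), sort(need)))
    stop_lotqa("lotqa_format_error",
               "sinogram CSV must have columns %s (got %s)",
               paste(need, collapse = ","), paste(names(df), collapse = ","))
  if (nrow(df) == 0)
    stop_lotqa("lotqa_format_error", "sinogram CSV has no event rows")
  if (length(unique(df$plan_id)) > 1 || length(unique(df$fraction)) > 1)
    stop_lotqa("lotqa_format_error",
               "one sinogram file must hold a single (plan_id, fraction)")
  n_leaves <- if (!is.null(meta$n_leaves)) as.integer(meta$n_leaves) else 64L
  if (any(df$leaf < 0 | df$leaf > n_leaves - 1))
    stop_lotqa("lotqa_validation_error", "leaf index outside [0, %d]",
               n_leaves - 1)
  if (any(df$projection < 0))
    stop_lotqa("lotqa_validation_error", "negative projection index")
  if (any(df$lot_ms < 0))
    stop_lotqa("lotqa_validation_error", "negative LOT value")
  dup <- duplicated(df[, c("projection", "leaf")])
  if (any(dup))
    stop_lotqa("lotqa_format_error",
               "duplicate (projection, leaf) event at data row %d",
               which(dup)[1])
  n_proj <- if (!is.null(meta$n_projections)) as.integer(meta$n_projections)
            else max(df$projection) + 1L
  dur <- if (!is.null(meta$projection_duration_ms))
    as.numeric(meta$projection_duration_ms)
  else if (!is.null(projection_duration_ms)) projection_duration_ms
  else stop_lotqa("lotqa_format_error",
                  "projection_duration_ms neither in file metadata nor supplied")
  if (max(df$projection) > n_proj - 1)
    stop_lotqa("lotqa_validation_error", "projection index outside [0, %d]",
               n_proj - 1)
  lot <- matrix(0, nrow = n_proj, ncol = n_leaves)
  lot[cbind(df$projection + 1L, df$leaf + 1L)] <- df$lot_ms
  site <- if (!is.null(meta$site)) meta$site else NA_character_
  frac <- df$fraction[1]
  if (frac == 0) {
    new_planned_sinogram(df$plan_id[1], site, lot, dur)
  } else {
    if (any(df$lot_ms > dur + 1e-9))
      stop_lotqa("lotqa_validation_error", "LOT exceeds projection duration")
    structure(list(plan_id = df$plan_id[1], site = site,
                   fraction_index = as.integer(frac), lot_ms = lot,
                   projection_duration_ms = dur,
                   sensor_resolution_ms =
                     if (!is.null(meta$sensor_resolution_ms))
                       as.numeric(meta$sensor_resolution_ms) else NA_real_,
                   detector_signal =
                     if (!is.null(meta$detector_signal))
                       as.numeric(meta$detector_signal) else NA_real_),
              class = "measured_sinogram")
  }
}

session_columns <- c("plan_id", "site", "fraction", "eta_percent",
                     "gamma_delta4", "gamma_film_cor", "gamma_film_sag",
                     "detector_signal", "phase")

#' Write a session table to CSV
#'
#' Fixed column order; percent columns serialized with 3 decimals,
#' detector signals with 6; missing optional values as empty fields.
#' Byte-stable for identical input.
#'
#' @param records Session data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_session_csv <- function(records, path) {
  req <- c("plan_id", "site", "fraction", "eta_percent")
  if (!all(req %in% names(records)))
    stop_lotqa("lotqa_parameter_error", "records need columns %s",
               paste(req, collapse = ", "))
  fmt_pct <- function(v) ifelse(is.na(v), "", sprintf("%.3f", v))
  out <- data.frame(plan_id = records$plan_id, site = records$site,
                    fraction = records$fraction,
                    eta_percent = fmt_pct(records$eta_percent),
                    stringsAsFactors = FALSE)
  for (col in c("gamma_delta4", "gamma_film_cor", "gamma_film_sag")) {
    out[[col]] <- if (col %in% names(records)) fmt_pct(records[[col]]) else ""
  }
  out$detector_signal <- if ("detector_signal" %in% names(records))
    ifelse(is.na(records$detector_signal), "",
           sprintf("%.6f", records$detector_signal)) else ""
  out$phase <- if ("phase" %in% names(records)) records$phase else "treatment"
  lines <- c(paste(session_columns, collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a session table from CSV
#'
#' Validates ranges (attainment and gamma pass rates in [0, 100]); missing
#' optional columns become absent (NA) fields rather than errors.
#'
#' @param path Input CSV path.
#' @return Session data.frame.
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path))
    stop_lotqa("lotqa_io_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("plan_id", "site", "fraction", "eta_percent")
  if (!all(req %in% names(df)))
    stop_lotqa("lotqa_format_error", "session CSV needs columns %s",
               paste(req, collapse = ", "))
  for (col in c("eta_percent", "gamma_delta4", "gamma_film_cor",
                "gamma_film_sag")) {
    if (!col %in% names(df)) { df[[col]] <- NA_real_; next }
    df[[col]] <- as.numeric(df[[col]])
    bad <- !is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 100)
    if (any(bad))
      stop_lotqa("lotqa_validation_error",
                 "%s outside [0, 100] at data row %d", col, which(bad)[1])
  }
  if (!"detector_signal" %in% names(df)) df$detector_signal <- NA_real_
  if (!"phase" %in% names(df)) df$phase <- "treatment"
  df[, session_columns]
}

#' Default cohort configuration
#'
#' Ships the six site archetypes (field width, pitch, modulation factor,
#' beam-on time, gantry period per site), a baseline error model, cohort
#' sizes and the analysis options, as one round-trippable list.
#'
#' @param seed Master seed stored in the config.
#' @return A cohort configuration list.
#' @export
default_cohort_config <- function(seed = 1L) {
  arche <- site_archetypes()
  sites <- lapply(seq_len(nrow(arche)), function(i)
    as.list(arche[i, c("field_width_cm", "pitch", "modulation_factor",
                       "beam_on_time_s", "gantry_period_s")]))
  names(sites) <- arche$site
  list(
    sites = sites,
    error_model = list(latency_mean_ms = 0.5, latency_sd_ms = 0.3,
                       jitter_sd_ms = 0.8, drop_probability = 0.002,
                       sensor_resolution_ms = 3.0, seed = as.integer(seed)),
    n_plans_per_site = 2L,
    n_fractions = 5L,
    bin_width_ms = 5,
    gamma_model = list(a = 0.2, noise_sd = 0.5),
    signal_noise_sd = 0.01,
    analysis = list(aggregation = "session", fence_multiplier = 1.5,
                    signal_threshold_z = 3, eta_threshold_z = 3),
    seed = as.integer(seed)
  )
}

config_keys <- function() {
  list(top = c("sites", "error_model", "n_plans_per_site", "n_fractions",
               "bin_width_ms", "gamma_model", "signal_noise_sd", "analysis",
               "seed"),
       site = c("field_width_cm", "pitch", "modulation_factor",
                "beam_on_time_s", "gantry_period_s"),
       error_model = c("latency_mean_ms", "latency_sd_ms", "jitter_sd_ms",
                       "drop_probability", "sensor_resolution_ms", "seed"),
       gamma_model = c("a", "noise_sd"),
       analysis = c("aggregation", "fence_multiplier", "signal_threshold_z",
                    "eta_threshold_z"))
}

#' Write a cohort configuration to JSON
#' @param config Configuration list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  validate_cohort_config(config)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a cohort configuration from JSON
#'
#' Unknown keys anywhere in the document are rejected so typos cannot
#' silently revert an option to its default.
#'
#' @param path Input JSON path.
#' @return A validated configuration list.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path))
    stop_lotqa("lotqa_io_error", "no such file: %s", path)
  config <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(config$sites)) {
    # jsonlite may simplify homogeneous site records; restore the list shape
    config$sites <- lapply(split(config$sites, rownames(config$sites)), as.list)
  }
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(config) {
  keys <- config_keys()
  check <- function(got, allowed, where) {
    extra <- setdiff(got, allowed)
    if (length(extra))
      stop_lotqa("lotqa_configuration_error", "unknown key(s) in %s: %s",
                 where, paste(extra, collapse = ", "))
  }
  check(names(config), keys$top, "config")
  for (s in names(config$sites))
    check(names(config$sites[[s]]), keys$site, paste0("sites$", s))
  check(names(config$error_model), keys$error_model, "error_model")
  check(names(config$gamma_model), keys$gamma_model, "gamma_model")
  check(names(config$analysis), keys$analysis, "analysis")
  invisible(config)
}
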