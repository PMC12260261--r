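#' Generate a multi-plan, multi-fraction delivery cohort
#'
#' Emits one planned sinogram per plan spec, \code{n_fractions} measured
#' sinograms per plan under that spec's error model, and a session table
#' with the attainment rate of every fraction precomputed, plus synthetic
#' gamma pass rates correlated with attainment and a relative detector
#' signal per session. Everything is derived deterministically from
#' \code{seed}.
#'
#' The synthetic gamma pass rates follow
#' \code{100 - a * (100 - eta_percent) + noise}, clamped to [0, 100]; they
#' exist to exercise the correlation machinery, not to model a measurement
#' system.
#'
#' @param site_specs List of specs, each a list with elements
#'   \code{params} (a \code{plan_parameters}), \code{model} (an
#'   \code{error_model}) and \code{n_fractions} (count >= 1).
#' @param seed Integer master seed.
#' @param bin_width_ms Difference-histogram bin width for the attainment
#'   computation (default 5 ms).
#' @param gamma_model List with \code{a} (attainment-to-gamma slope) and
#'   \code{noise_sd}; set \code{a = 0} for uncorrelated gammas.
#' @param signal_noise_sd SD of the detector-signal baseline noise.
#' @return A list with \code{planned} (list of planned sinograms),
#'   \code{measured} (flat list of measured sinograms) and \code{sessions}
#'   (data.frame: plan_id, site, fraction, eta_percent, gamma_delta4,
#'   gamma_film_cor, gamma_film_sag, detector_signal, phase).
#' @export
generate_cohort <- function(site_specs, seed, bin_width_ms = 5,
                            gamma_model = list(a = 0.2, noise_sd = 0.5),
                            signal_noise_sd = 0.01) {
  if (!is.list(site_specs) || length(site_specs) == 0)
    stop_lotqa("lotqa_parameter_error", "site_specs must be a non-empty list")
  planned <- list()
  measured <- list()
  rows <- list()
  for (i in seq_along(site_specs)) {
    spec <- site_specs[[i]]
    stopifnot(inherits(spec$params, "plan_parameters"),
              inherits(spec$model, "error_model"))
    if (!is_count(spec$n_fractions) || spec$n_fractions < 1)
      stop_lotqa("lotqa_parameter_error", "n_fractions must be a count >= 1")
    plan <- generate_plan(spec$params, derive_seed(seed, i))
    planned[[plan$plan_id]] <- plan
    model <- spec$model
    model$seed <- derive_seed(seed, 10000 + i)
    aux <- withr::with_seed(derive_seed(seed, 20000 + i), list(
      signal_noise = stats::rnorm(spec$n_fractions, 0, signal_noise_sd),
      gamma_noise = matrix(stats::rnorm(3 * spec$n_fractions, 0,
                                        gamma_model$noise_sd),
                           ncol = 3)
    ))
    for (f in seq_len(spec$n_fractions)) {
      signal <- 1 + aux$signal_noise[f]
      meas <- apply_error_model(plan, model, f, detector_signal = signal)
      measured[[length(measured) + 1L]] <- meas
      eta <- attainment_rate(difference_histogram(plan, meas, bin_width_ms))
      gm <- 100 - gamma_model$a * (100 - eta$eta_percent) + aux$gamma_noise[f, ]
      gm <- pmin(pmax(gm, 0), 100)
      rows[[length(rows) + 1L]] <- data.frame(
        plan_id = plan$plan_id, site = plan$site, fraction = f,
        eta_percent = eta$eta_percent,
        gamma_delta4 = gm[1], gamma_film_cor = gm[2], gamma_film_sag = gm[3],
        detector_signal = signal, phase = "treatment",
        stringsAsFactors = FALSE)
    }
  }
  list(planned = planned, measured = measured,
       sessions = do.call(rbind, rows))
}

#' Build cohort specs from a cohort configuration
#'
#' Expands a configuration (see \code{\link{default_cohort_config}}) into
#' the per-plan spec list consumed by \code{\link{generate_cohort}}:
#' \code{n_plans_per_site} plans for each configured site archetype, all
#' sharing the configured error model.
#'
#' @param config A cohort configuration list.
#' @return List of specs for \code{\link{generate_cohort}}.
#' @export
cohort_specs_from_config <- function(config) {
  specs <- list()
  em <- do.call(error_model, config$error_model)
  for (site in names(config$sites)) {
    arche <- config$sites[[site]]
    for (p in seq_len(config$n_plans_per_site)) {
      params <- plan_parameters(
        plan_id = sprintf("%s_%02d", site, p), site = site,
        field_width_cm = arche$field_width_cm, pitch = arche$pitch,
        modulation_factor = arche$modulation_factor,
        gantry_period_s = arche$gantry_period_s,
        beam_on_time_s = arche$beam_on_time_s)
      specs[[length(specs) + 1L]] <-
        list(params = params, model = em, n_fractions = config$n_fractions)
    }
  }
  specs
}
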