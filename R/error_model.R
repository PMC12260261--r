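#' Leaf-timing error model
#'
#' Parameterizes how measured leaf-open times deviate from planned ones:
#' a systematic latency (drawn once per fraction), per-event jitter,
#' random dropped openings, and quantization at the optical position
#' sensor's temporal resolution (~3.0 ms on this platform).
#'
#' @param latency_mean_ms Mean systematic shift, ms.
#' @param latency_sd_ms SD of the per-fraction systematic shift, ms, >= 0.
#' @param jitter_sd_ms SD of per-event timing noise, ms, >= 0.
#' @param drop_probability Probability a planned opening is not executed
#'   (measured LOT 0), in [0, 1].
#' @param sensor_resolution_ms Sensor temporal resolution, ms, > 0;
#'   measured LOTs are quantized to multiples of this value.
#' @param seed Integer seed; combined with the fraction index so each
#'   fraction is reproducible.
#' @return An object of class \code{error_model}.
#' @export
error_model <- function(latency_mean_ms = 0, latency_sd_ms = 0,
                        jitter_sd_ms = 0, drop_probability = 0,
                        sensor_resolution_ms = 3.0, seed = 1L) {
  if (latency_sd_ms < 0 || jitter_sd_ms < 0)
    stop_lotqa("lotqa_parameter_error", "SDs must be >= 0")
  if (drop_probability < 0 || drop_probability > 1)
    stop_lotqa("lotqa_parameter_error", "drop_probability must be in [0, 1]")
  if (sensor_resolution_ms <= 0)
    stop_lotqa("lotqa_parameter_error", "sensor_resolution_ms must be > 0")
  structure(list(latency_mean_ms = latency_mean_ms,
                 latency_sd_ms = latency_sd_ms,
                 jitter_sd_ms = jitter_sd_ms,
                 drop_probability = drop_probability,
                 sensor_resolution_ms = sensor_resolution_ms,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Simulate a telemetry-measured sinogram from a planned one
#'
#' For each planned opening (planned LOT > 0): with probability
#' \code{drop_probability} the opening is dropped (measured LOT 0);
#' otherwise measured = planned + fraction-level latency + per-event
#' jitter, clamped to [0, projection duration], then quantized to the
#' nearest multiple of the sensor resolution (ties round half away from
#' zero). Entries that are zero in the plan stay zero. The latency draw is
#' shared by all events of a fraction; jitter is drawn per event. Draws use
#' fixed-count standard-normal/uniform streams so that runs with the same
#' \code{model$seed} and \code{fraction_index} but different SDs share
#' common random numbers.
#'
#' @param plan A \code{planned_sinogram}.
#' @param model An \code{error_model}.
#' @param fraction_index Fraction number, >= 1.
#' @param detector_signal Relative exit-detector signal to attach
#'   (baseline 1.0).
#' @return An object of class \code{measured_sinogram}.
#' @export
apply_error_model <- function(plan, model, fraction_index = 1L,
                              detector_signal = 1.0) {
  stopifnot(inherits(plan, "planned_sinogram"), inherits(model, "error_model"))
  if (!is_count(fraction_index) || fraction_index < 1)
    stop_lotqa("lotqa_parameter_error", "fraction_index must be a count >= 1")
  dur <- plan$projection_duration_ms
  res <- model$sensor_resolution_ms
  idx <- which(plan$lot_ms > 0)
  draws <- error_draws(model$seed, fraction_index, length(idx))
  latency <- model$latency_mean_ms + model$latency_sd_ms * draws$latency_z
  raw <- plan$lot_ms[idx] + latency + model$jitter_sd_ms * draws$jitter_z
  raw <- pmin(pmax(raw, 0), dur)
  q <- quantize_ms(raw, res)
  q <- pmin(q, floor(dur / res + 1e-9) * res)  # keep within projection
  q[draws$drop_u < model$drop_probability] <- 0
  lot <- plan$lot_ms
  lot[] <- 0
  lot[idx] <- q
  structure(list(plan_id = plan$plan_id, site = plan$site,
                 fraction_index = as.integer(fraction_index),
                 lot_ms = lot, projection_duration_ms = dur,
                 sensor_resolution_ms = res,
                 detector_signal = detector_signal),
            class = "measured_sinogram")
}

# The raw random streams behind apply_error_model, exposed internally so
# tests can re-derive the exact pre-quantization draws.
error_draws <- function(seed, fraction_index, n_events) {
  withr::with_seed(derive_seed(seed, fraction_index), {
    list(latency_z = stats::rnorm(1),
         jitter_z = stats::rnorm(n_events),
         drop_u = stats::runif(n_events))
  })
}

#' @export
print.measured_sinogram <- function(x, ...) {
  nz <- sum(x$lot_ms > 0)
  cat(sprintf("<measured_sinogram> %s fraction %d: %d openings, signal %.3f\n",
              x$plan_id, x$fraction_index, nz, x$detector_signal))
  invisible(x)
}

#' Simulate an exit-detector signal trend across fractions
#'
#' Baseline relative detector signal near 1.0 with Gaussian noise; the
#' listed anomaly fractions are depressed by a multiplicative factor
#' (1 - \code{anomaly_depth}), emulating fractions where the exit signal
#' and the attainment rate co-decline.
#'
#' @param n_fractions Number of fractions.
#' @param anomaly_fractions Integer vector of fraction numbers (1-based)
#'   to depress; may be empty.
#' @param anomaly_depth Fractional depression in [0, 1).
#' @param noise_sd SD of the baseline signal noise.
#' @param seed Integer seed.
#' @return Numeric vector of length \code{n_fractions}.
#' @export
generate_detector_trend <- function(n_fractions, anomaly_fractions = integer(),
                                    anomaly_depth = 0, noise_sd = 0.01,
                                    seed = 1L) {
  if (!is_count(n_fractions) || n_fractions < 1)
    stop_lotqa("lotqa_parameter_error", "n_fractions must be a count >= 1")
  if (length(anomaly_fractions) &&
      (any(anomaly_fractions < 1) || any(anomaly_fractions > n_fractions)))
    stop_lotqa("lotqa_parameter_error",
               "anomaly_fractions must lie in 1..n_fractions")
  if (anomaly_depth < 0 || anomaly_depth >= 1)
    stop_lotqa("lotqa_parameter_error", "anomaly_depth must be in [0, 1)")
  sig <- withr::with_seed(seed, 1 + stats::rnorm(n_fractions, 0, noise_sd))
  sig[anomaly_fractions] <- sig[anomaly_fractions] * (1 - anomaly_depth)
  sig
}

#' Simulate a fraction series with detector/attainment co-decline
#'
#' End-to-end scenario generator for trend monitoring: one plan delivered
#' over \code{n_fractions}, with the anomaly fractions receiving both a
#' depressed detector signal (via \code{\link{generate_detector_trend}})
#' and inflated leaf-timing jitter (extra \code{60 * anomaly_depth} ms of
#' per-event jitter SD), so the attainment rate co-declines with the exit
#' signal on those fractions.
#'
#' @param params A \code{plan_parameters} object.
#' @param base_model The \code{error_model} for unaffected fractions.
#' @param n_fractions Number of fractions.
#' @param anomaly_fractions Fraction numbers to perturb.
#' @param anomaly_depth Fractional signal depression in [0, 1).
#' @param noise_sd Detector-signal noise SD.
#' @param bin_width_ms Difference-histogram bin width used to compute the
#'   attainment rate.
#' @param seed Integer seed.
#' @return A data.frame with columns \code{plan_id}, \code{site},
#'   \code{fraction}, \code{eta_percent}, \code{detector_signal}.
#' @export
simulate_trend_scenario <- function(params, base_model, n_fractions,
                                    anomaly_fractions = integer(),
                                    anomaly_depth = 0, noise_sd = 0.01,
                                    bin_width_ms = 5, seed = 1L) {
  plan <- generate_plan(params, derive_seed(seed, 1))
  signals <- generate_detector_trend(n_fractions, anomaly_fractions,
                                     anomaly_depth, noise_sd,
                                     derive_seed(seed, 2))
  model <- base_model
  model$seed <- derive_seed(seed, 3)
  anomaly_model <- model
  anomaly_model$jitter_sd_ms <- model$jitter_sd_ms + 60 * anomaly_depth
  rows <- lapply(seq_len(n_fractions), function(f) {
    m <- if (f %in% anomaly_fractions) anomaly_model else model
    meas <- apply_error_model(plan, m, f, detector_signal = signals[f])
    eta <- attainment_rate(difference_histogram(plan, meas, bin_width_ms))
    data.frame(plan_id = plan$plan_id, site = plan$site, fraction = f,
               eta_percent = eta$eta_percent, detector_signal = signals[f],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
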