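#' Plan parameters for a helical binary-MLC delivery
#'
#' Bundles the treatment-plan-level parameters that determine the geometry
#' and timing of a helical tomotherapy delivery: field width, pitch,
#' modulation factor (maximum nonzero leaf-open time divided by the mean
#' nonzero leaf-open time), beam-on time and gantry rotation period. The
#' projection duration is \code{gantry_period_s / projections_per_rotation}
#' and the number of projections is \code{round(beam_on_time_s /
#' projection_duration)}.
#'
#' @param plan_id Character identifier for the plan.
#' @param site One of \code{"prostate"}, \code{"pelvis"}, \code{"head"},
#'   \code{"chest"}, \code{"hn"}, \code{"sbrt"}.
#' @param field_width_cm Jaw field width in cm.
#' @param pitch Couch travel per rotation divided by field width; must be
#'   positive.
#' @param modulation_factor Target ratio max/mean of the nonzero leaf-open
#'   times; must be >= 1.
#' @param gantry_period_s Gantry rotation period in seconds, > 0.
#' @param beam_on_time_s Total beam-on time in seconds, > 0.
#' @param n_leaves Number of binary MLC leaves (64 on this platform).
#' @param projections_per_rotation Angular segments per rotation (51).
#' @param open_leaf_band Length-2 integer vector of 0-based leaf indices
#'   (inclusive) delimiting the leaves eligible to open; defaults to the
#'   central half of the leaf bank.
#' @param open_fraction Probability that an eligible leaf opens in a given
#'   projection when simulating a plan.
#' @return An object of class \code{plan_parameters}.
#' @export
plan_parameters <- function(plan_id, site,
                            field_width_cm = 2.5,
                            pitch = 0.4,
                            modulation_factor = 2.0,
                            gantry_period_s = 20.0,
                            beam_on_time_s = 250.0,
                            n_leaves = 64L,
                            projections_per_rotation = 51L,
                            open_leaf_band = NULL,
                            open_fraction = 0.7) {
  site <- match.arg(site, c("prostate", "pelvis", "head", "chest", "hn", "sbrt"))
  if (!is.numeric(modulation_factor) || modulation_factor < 1)
    stop_lotqa("lotqa_parameter_error", "modulation_factor must be >= 1 (got %s)",
               format(modulation_factor))
  if (pitch <= 0) stop_lotqa("lotqa_parameter_error", "pitch must be > 0")
  if (gantry_period_s <= 0)
    stop_lotqa("lotqa_parameter_error", "gantry_period_s must be > 0")
  if (beam_on_time_s <= 0)
    stop_lotqa("lotqa_parameter_error", "beam_on_time_s must be > 0")
  if (!is_count(n_leaves) || n_leaves < 1)
    stop_lotqa("lotqa_parameter_error", "n_leaves must be a positive count")
  if (!is_count(projections_per_rotation) || projections_per_rotation < 1)
    stop_lotqa("lotqa_parameter_error", "projections_per_rotation must be a positive count")
  if (is.null(open_leaf_band)) {
    half <- n_leaves / 4
    open_leaf_band <- c(floor(half), n_leaves - 1 - floor(half))
  }
  if (length(open_leaf_band) != 2 || open_leaf_band[1] > open_leaf_band[2] ||
      open_leaf_band[1] < 0 || open_leaf_band[2] > n_leaves - 1)
    stop_lotqa("lotqa_parameter_error", "open_leaf_band must be 0-based indices within the leaf bank")
  if (open_fraction <= 0 || open_fraction > 1)
    stop_lotqa("lotqa_parameter_error", "open_fraction must be in (0, 1]")
  p <- list(plan_id = as.character(plan_id), site = site,
            field_width_cm = field_width_cm, pitch = pitch,
            modulation_factor = modulation_factor,
            gantry_period_s = gantry_period_s,
            beam_on_time_s = beam_on_time_s,
            n_leaves = as.integer(n_leaves),
            projections_per_rotation = as.integer(projections_per_rotation),
            open_leaf_band = as.integer(open_leaf_band),
            open_fraction = open_fraction)
  if (n_projections_of(p) < 1)
    stop_lotqa("lotqa_parameter_error",
               "plan %s yields zero projections (beam_on_time_s too short)", plan_id)
  class(p) <- "plan_parameters"
  p
}

#' @export
print.plan_parameters <- function(x, ...) {
  cat(sprintf("<plan_parameters> %s (%s): pitch %.3f, MF %.3f, beam-on %.1f s, gantry %.2f s\n",
              x$plan_id, x$site, x$pitch, x$modulation_factor,
              x$beam_on_time_s, x$gantry_period_s))
  cat(sprintf("  %d leaves, %d projections/rotation -> %d projections of %.2f ms\n",
              x$n_leaves, x$projections_per_rotation, n_projections_of(x),
              projection_duration_ms_of(x)))
  invisible(x)
}

#' Projection duration in milliseconds implied by a plan
#' @param params A \code{plan_parameters} object.
#' @return Milliseconds per projection.
#' @export
projection_duration_ms_of <- function(params) {
  params$gantry_period_s / params$projections_per_rotation * 1000
}

#' Number of projections implied by a plan
#' @param params A \code{plan_parameters} object.
#' @return Integer projection count \code{round(beam_on_time_s / projection_duration)}.
#' @export
n_projections_of <- function(params) {
  as.integer(round(params$beam_on_time_s /
                     (params$gantry_period_s / params$projections_per_rotation)))
}

#' Per-site plan archetypes
#'
#' Cohort-mean plan parameters for the six treatment-site archetypes used
#' by the synthetic delivery generator: field width, pitch, modulation
#' factor, beam-on time and gantry period per site.
#'
#' @return A data.frame with one row per site.
#' @export
site_archetypes <- function() {
  data.frame(
    site = c("prostate", "pelvis", "head", "chest", "hn", "sbrt"),
    field_width_cm = rep(2.5, 6),
    pitch = c(0.414, 0.437, 0.442, 0.433, 0.433, 0.178),
    modulation_factor = c(2.0000, 2.1000, 2.4286, 2.0333, 2.6400, 2.0000),
    beam_on_time_s = c(238.18, 302.01, 154.07, 330.88, 273.68, 450.93),
    gantry_period_s = c(27.17, 16.34, 14.51, 17.15, 14.68, 33.18),
    stringsAsFactors = FALSE
  )
}

#' Plan parameters for a named site archetype
#'
#' @param site Site name (see \code{\link{site_archetypes}}).
#' @param plan_id Identifier for the plan; defaults to the site name.
#' @param ... Overrides passed to \code{\link{plan_parameters}}.
#' @return A \code{plan_parameters} object.
#' @export
archetype_parameters <- function(site, plan_id = site, ...) {
  tab <- site_archetypes()
  row <- tab[tab$site == site, , drop = FALSE]
  if (nrow(row) != 1)
    stop_lotqa("lotqa_parameter_error", "unknown site archetype '%s'", site)
  args <- list(plan_id = plan_id, site = site,
               field_width_cm = row$field_width_cm, pitch = row$pitch,
               modulation_factor = row$modulation_factor,
               gantry_period_s = row$gantry_period_s,
               beam_on_time_s = row$beam_on_time_s)
  override <- list(...)
  args[names(override)] <- override
  do.call(plan_parameters, args)
}

#' Generate a planned leaf-open-time sinogram
#'
#' Simulates a planned sinogram (projection x leaf matrix of leaf-open
#' times, ms) for a plan. Leaves inside \code{open_leaf_band} open in each
#' projection with probability \code{open_fraction}; nonzero leaf-open
#' times are drawn from a scaled beta distribution and affinely rescaled so
#' the realized modulation factor (max nonzero LOT / mean nonzero LOT)
#' equals the requested one. The maximum LOT is capped at 95% of the
#' projection duration.
#'
#' @param params A \code{plan_parameters} object.
#' @param seed Integer seed; the same seed reproduces the same sinogram.
#' @return An object of class \code{planned_sinogram} with fields
#'   \code{plan_id}, \code{site}, \code{lot_ms} (matrix) and
#'   \code{projection_duration_ms}.
#' @export
generate_plan <- function(params, seed) {
  stopifnot(inherits(params, "plan_parameters"))
  dur <- projection_duration_ms_of(params)
  n_proj <- n_projections_of(params)
  band <- params$open_leaf_band + 1L  # to 1-based columns
  leaves <- band[1]:band[2]
  mf <- params$modulation_factor
  lot <- withr::with_seed(seed, {
    m <- matrix(0, nrow = n_proj, ncol = params$n_leaves)
    open <- matrix(stats::runif(n_proj * length(leaves)) < params$open_fraction,
                   nrow = n_proj)
    if (!any(open)) open[1, 1] <- TRUE  # guarantee at least one opening
    n_open <- sum(open)
    if (mf == 1) {
      vals <- rep(0.5 * dur, n_open)
    } else {
      y <- stats::rbeta(n_open, 0.8, 3)
      # affine map lot = s*(y + c) makes max/mean hit mf exactly; requires
      # max(y) > mf*mean(y), which the long beta tail gives except at tiny n
      if (max(y) <= mf * mean(y)) y[which.max(y)] <- mf * mean(y) * 1.05
      cc <- (max(y) - mf * mean(y)) / (mf - 1)
      vals <- (y + cc) / (max(y) + cc) * 0.95 * dur
    }
    m[, leaves][open] <- vals
    m
  })
  new_planned_sinogram(params$plan_id, params$site, lot, dur)
}

new_planned_sinogram <- function(plan_id, site, lot_ms, projection_duration_ms) {
  stopifnot(is.matrix(lot_ms))
  if (any(lot_ms < 0) || any(lot_ms > projection_duration_ms + 1e-9))
    stop_lotqa("lotqa_validation_error",
               "planned LOTs must lie in [0, projection duration]")
  if (!any(lot_ms > 0))
    stop_lotqa("lotqa_validation_error", "planned sinogram has no openings")
  structure(list(plan_id = plan_id, site = site, lot_ms = lot_ms,
                 projection_duration_ms = projection_duration_ms),
            class = "planned_sinogram")
}

#' @export
print.planned_sinogram <- function(x, ...) {
  nz <- sum(x$lot_ms > 0)
  cat(sprintf("<planned_sinogram> %s: %d x %d, %d openings, projection %.2f ms\n",
              x$plan_id, nrow(x$lot_ms), ncol(x$lot_ms), nz,
              x$projection_duration_ms))
  invisible(x)
}

#' Realized modulation factor of a sinogram
#'
#' Ratio of the maximum nonzero leaf-open time to the mean nonzero
#' leaf-open time.
#'
#' @param sinogram A planned or measured sinogram.
#' @return The realized modulation factor (NA if no openings).
#' @export
realized_modulation_factor <- function(sinogram) {
  v <- sinogram$lot_ms[sinogram$lot_ms > 0]
  if (length(v) == 0) return(NA_real_)
  max(v) / mean(v)
}
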