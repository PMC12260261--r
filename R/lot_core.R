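#' Leaf-open-time histogram
#'
#' Bins the nonzero leaf-open times of a sinogram into right-open bins
#' \code{[k*w, (k+1)*w)} over \code{[0, projection duration]} (a value
#' exactly at the top edge falls in the last bin). Zero-LOT entries are
#' closed leaves and are excluded from both the counts and the event total.
#'
#' @param sinogram A \code{planned_sinogram} or \code{measured_sinogram}.
#' @param bin_width_ms Bin width in ms, > 0.
#' @return An object of class \code{lot_histogram} with \code{bin_edges_ms},
#'   \code{counts} and \code{total_events}.
#' @export
build_lot_histogram <- function(sinogram, bin_width_ms) {
  if (bin_width_ms <= 0)
    stop_lotqa("lotqa_parameter_error", "bin_width_ms must be > 0")
  dur <- sinogram$projection_duration_ms
  v <- sinogram$lot_ms[sinogram$lot_ms > 0]
  nb <- max(1L, as.integer(ceiling(dur / bin_width_ms)))
  edges <- (0:nb) * bin_width_ms
  k <- pmin(as.integer(floor(v / bin_width_ms)) + 1L, nb)
  counts <- tabulate(k, nbins = nb)
  structure(list(bin_edges_ms = edges, counts = counts,
                 total_events = length(v)),
            class = "lot_histogram")
}

#' @export
print.lot_histogram <- function(x, ...) {
  cat(sprintf("<lot_histogram> %d events in %d bins of %.2f ms\n",
              x$total_events, length(x$counts),
              diff(x$bin_edges_ms[1:2])))
  invisible(x)
}

#' Planned-vs-measured leaf-open-time difference histogram
#'
#' Pairs every planned opening (planned LOT > 0) with the measured LOT at
#' the same (projection, leaf) cell and bins the signed difference
#' \code{measured - planned} onto a symmetric grid of bins centered at
#' multiples of \code{bin_width_ms}, the zero bin covering
#' \code{|difference| <= bin_width_ms / 2} (boundary ties resolve toward
#' zero). A dropped opening (measured 0 where planned > 0) contributes its
#' full negative difference. Measured openings where the plan is closed are
#' counted separately as \code{extra_measured} and never enter the
#' histogram or the attainment denominator. Differences beyond the grid go
#' to two overflow bins so the counts always sum to the planned-opening
#' total.
#'
#' @param planned A \code{planned_sinogram}.
#' @param measured A \code{measured_sinogram} of the same shape.
#' @param bin_width_ms Bin width in ms (default 5, giving a zero-attainment
#'   tolerance of +/- 2.5 ms).
#' @param n_bins_side Number of bins on each side of zero (default 20).
#' @return An object of class \code{diff_histogram} with
#'   \code{bin_centers_ms}, \code{counts}, \code{overflow_neg},
#'   \code{overflow_pos}, \code{zero_count}, \code{total_planned_events},
#'   \code{extra_measured} and \code{bin_width_ms}.
#' @export
difference_histogram <- function(planned, measured, bin_width_ms = 5,
                                 n_bins_side = 20L) {
  if (bin_width_ms <= 0)
    stop_lotqa("lotqa_parameter_error", "bin_width_ms must be > 0")
  if (!identical(dim(planned$lot_ms), dim(measured$lot_ms)))
    stop_lotqa("lotqa_structural_error",
               "shape mismatch: planned %d x %d vs measured %d x %d",
               nrow(planned$lot_ms), ncol(planned$lot_ms),
               nrow(measured$lot_ms), ncol(measured$lot_ms))
  p <- planned$lot_ms
  m <- measured$lot_ms
  open <- p > 0
  d <- m[open] - p[open]
  # nearest-center binning with half-width ties toward zero
  k <- sign(d) * ceiling(abs(d) / bin_width_ms - 0.5)
  K <- as.integer(n_bins_side)
  centers <- (-K:K) * bin_width_ms
  inside <- abs(k) <= K
  counts <- tabulate(as.integer(k[inside]) + K + 1L, nbins = 2L * K + 1L)
  structure(list(bin_width_ms = bin_width_ms,
                 bin_centers_ms = centers,
                 counts = counts,
                 overflow_neg = sum(k < -K),
                 overflow_pos = sum(k > K),
                 zero_count = counts[K + 1L],
                 total_planned_events = sum(open),
                 extra_measured = sum(m > 0 & !open)),
            class = "diff_histogram")
}

#' @export
print.diff_histogram <- function(x, ...) {
  cat(sprintf("<diff_histogram> %d planned openings, zero bin %d, bin width %.1f ms\n",
              x$total_planned_events, x$zero_count, x$bin_width_ms))
  if (x$extra_measured > 0)
    cat(sprintf("  %d extra measured openings (planned closed) excluded\n",
                x$extra_measured))
  invisible(x)
}

#' Leaf-open-time attainment rate
#'
#' The attainment rate is the zero bin of the difference histogram divided
#' by its integral over all bins: the fraction of planned leaf openings
#' whose measured timing matched the plan within half a bin width. The
#' denominator is the total number of planned openings, including those the
#' MLC failed to execute.
#'
#' @param x A \code{diff_histogram}, or a numeric zero-bin count (in which
#'   case \code{total} must be given).
#' @param total Total planned-opening count when \code{x} is numeric.
#' @return An object of class \code{attainment_result} with \code{eta}
#'   (fraction), \code{eta_percent} (rounded to 3 decimals),
#'   \code{zero_count} and \code{total_planned_events}.
#' @export
attainment_rate <- function(x, total = NULL) {
  if (inherits(x, "diff_histogram")) {
    zero_count <- x$zero_count
    total <- x$total_planned_events
  } else {
    if (is.null(total))
      stop_lotqa("lotqa_parameter_error",
                 "total must be supplied when x is a raw zero-bin count")
    zero_count <- x
  }
  if (!is_count(zero_count) || !is_count(total))
    stop_lotqa("lotqa_parameter_error", "counts must be non-negative integers")
  if (total == 0)
    stop_lotqa("lotqa_undefined_statistic_error",
               "attainment rate undefined: no planned openings (empty or all-zero plan)")
  if (zero_count > total)
    stop_lotqa("lotqa_validation_error", "zero_count exceeds the planned total")
  eta <- zero_count / total
  structure(list(eta = eta, eta_percent = round(100 * eta, 3),
                 zero_count = as.integer(zero_count),
                 total_planned_events = as.integer(total)),
            class = "attainment_result")
}

#' @export
print.attainment_result <- function(x, ...) {
  cat(sprintf("LOT attainment rate: %.3f%% (%d/%d)\n",
              x$eta_percent, x$zero_count, x$total_planned_events))
  invisible(x)
}
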