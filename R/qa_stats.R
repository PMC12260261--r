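#' Box-plot IQR outlier screen
#'
#' Computes quartiles by linear interpolation of order statistics
#' (\code{stats::quantile} type 7), fences at Q1 - k*IQR and Q3 + k*IQR,
#' and flags values strictly outside the fences. Low-side outliers mark
#' attainment-degrading sessions.
#'
#' @param values Numeric vector, length >= 4.
#' @param fence_multiplier Whisker multiplier k (default 1.5).
#' @return A list with \code{iqr}, \code{fences} (length 2), \code{outliers}
#'   (integer indices into \code{values}) and \code{low_side} (logical,
#'   parallel to \code{outliers}).
#' @export
iqr_outliers <- function(values, fence_multiplier = 1.5) {
  if (length(values) < 4)
    stop_lotqa("lotqa_insufficient_data_error",
               "need at least 4 values for IQR outlier screening (got %d)",
               length(values))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - fence_multiplier * iqr, q[2] + fence_multiplier * iqr)
  idx <- which(values < fences[1] | values > fences[2])
  list(iqr = iqr, fences = fences, outliers = idx,
       low_side = values[idx] < fences[1])
}

#' Aggregate attainment sessions into group summaries
#'
#' Pools sessions within each group (by plan, by site, or all together)
#' and reports n, mean, sample SD, IQR and IQR-fence outliers. With
#' \code{aggregation = "plan"} the pooled values are per-plan means rather
#' than raw sessions.
#'
#' @param records Data.frame of session records with at least
#'   \code{plan_id}, \code{site}, \code{fraction} and \code{eta_percent}.
#' @param group_by One of \code{"site"}, \code{"plan"}, \code{"all"}.
#' @param aggregation \code{"session"} (default) pools sessions;
#'   \code{"plan"} pools per-plan means.
#' @param fence_multiplier IQR fence multiplier.
#' @return A data.frame with one row per group: \code{group_label},
#'   \code{n}, \code{mean}, \code{sd}, \code{iqr}, and a list-column
#'   \code{outliers} of data.frames (\code{plan_id}, \code{fraction},
#'   \code{eta_percent}).
#' @export
summarize_sessions <- function(records, group_by = c("site", "plan", "all"),
                               aggregation = c("session", "plan"),
                               fence_multiplier = 1.5) {
  group_by <- match.arg(group_by)
  aggregation <- match.arg(aggregation)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_lotqa("lotqa_parameter_error", "records must be a non-empty data.frame")
  if (any(!is.finite(records$eta_percent)))
    stop_lotqa("lotqa_validation_error", "every record needs a finite eta_percent")
  key <- switch(group_by,
                site = records$site,
                plan = records$plan_id,
                all = rep("all", nrow(records)))
  labels <- sort(unique(key))
  out <- lapply(labels, function(lab) {
    g <- records[key == lab, , drop = FALSE]
    if (aggregation == "plan") {
      means <- tapply(g$eta_percent, g$plan_id, mean)
      vals <- as.numeric(means)
      ids <- names(means)
      fracs <- rep(NA_integer_, length(vals))
    } else {
      vals <- g$eta_percent
      ids <- g$plan_id
      fracs <- g$fraction
    }
    n <- length(vals)
    if (n == 1) {
      warning(sprintf("group '%s' has a single value; SD reported as 0", lab),
              call. = FALSE)
      sdv <- 0
    } else sdv <- stats::sd(vals)
    iqr <- if (n >= 2)
      diff(stats::quantile(vals, c(0.25, 0.75), type = 7, names = FALSE))
    else 0
    if (n >= 4) {
      sc <- iqr_outliers(vals, fence_multiplier)
      oidx <- sc$outliers
    } else oidx <- integer()
    data.frame(group_label = lab, n = n, mean = mean(vals), sd = sdv,
               iqr = iqr,
               outliers = I(list(data.frame(plan_id = ids[oidx],
                                            fraction = fracs[oidx],
                                            eta_percent = vals[oidx],
                                            stringsAsFactors = FALSE))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Five-level correlation strength classification
#'
#' Maps \code{|rho|} to \code{very_weak} (< 0.2), \code{weak} (< 0.4),
#' \code{moderate} (< 0.6), \code{strong} (< 0.8) or \code{very_strong}
#' (>= 0.8); intervals are right-open at the cutpoints.
#'
#' @param rho Correlation coefficient in [-1, 1].
#' @return One of the five strength labels.
#' @export
classify_correlation <- function(rho) {
  a <- abs(rho)
  if (!is.finite(a) || a > 1 + 1e-12)
    stop_lotqa("lotqa_parameter_error", "rho must lie in [-1, 1]")
  if (a < 0.2) "very_weak"
  else if (a < 0.4) "weak"
  else if (a < 0.6) "moderate"
  else if (a < 0.8) "strong"
  else "very_strong"
}

# All permutations of 1..n as an (n!) x n integer matrix.
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  m <- nrow(sub)
  res <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    block <- sub + (sub >= i)  # remap 1..n-1 to 1..n skipping i
    res[((i - 1L) * m + 1L):(i * m), ] <- cbind(rep(i, m), block)
  }
  res
}

#' Spearman rank correlation with strength classification
#'
#' Ranks use average ties; rho is the Pearson correlation of the ranks.
#' The two-sided p-value is an exact permutation p for n <= 9 (all n!
#' permutations of one rank vector, so ties are handled exactly) and the
#' t-approximation \code{t = rho * sqrt((n-2)/(1-rho^2))} on n - 2 degrees
#' of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return An object of class \code{correlation_result} with \code{rho},
#'   \code{p_value}, \code{strength} and \code{n}.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n)
    stop_lotqa("lotqa_parameter_error", "x and y must have equal length")
  if (n < 3)
    stop_lotqa("lotqa_insufficient_data_error", "need n >= 3 (got %d)", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_lotqa("lotqa_validation_error", "inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_lotqa("lotqa_undefined_statistic_error",
               "correlation undefined for a constant sequence")
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 9) {
    rx <- rank(x); ry <- rank(y)
    rxc <- rx - mean(rx); ryc <- ry - mean(ry)
    P <- permutations_all(n)
    M <- matrix(ryc[P], nrow = nrow(P))
    rhos <- as.vector(M %*% rxc) / sqrt(sum(rxc^2) * sum(ryc^2))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (abs(rho) == 1) 0 else 2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(rho = rho, p_value = p,
                 strength = classify_correlation(rho), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (%s), p = %.4g, n = %d\n",
              x$rho, x$strength, x$p_value, x$n))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sample comparison of means without the equal-variance assumption,
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value.
#' Delegates to \code{stats::t.test(var.equal = FALSE)}.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return An object of class \code{welch_result} with \code{t_statistic},
#'   \code{df} and \code{p_value}.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_lotqa("lotqa_insufficient_data_error", "both samples need n >= 2")
  if (any(!is.finite(c(a, b))))
    stop_lotqa("lotqa_validation_error", "inputs must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_lotqa("lotqa_undefined_statistic_error",
               "t undefined: both samples have zero variance%s",
               if (mean(a) == mean(b)) " and equal means" else "")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Welch tests of each site against the pooled cohort
#'
#' For each site and each metric column, runs Welch's t-test of that
#' site's sessions against all sessions pooled, producing the site-by-
#' metric p-value matrix used to ask which sites differ from the cohort
#' mean.
#'
#' @param records Session data.frame with a \code{site} column.
#' @param metrics Character vector of metric column names
#'   (default \code{"eta_percent"}).
#' @param p_adjust Multiple-testing correction passed to
#'   \code{stats::p.adjust} (\code{"none"} by default, \code{"holm"}
#'   available).
#' @return A data.frame with columns \code{site}, \code{metric},
#'   \code{n_site}, \code{n_all}, \code{t_statistic}, \code{df},
#'   \code{p_value}.
#' @export
site_vs_all_tests <- function(records, metrics = "eta_percent",
                              p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  missing_cols <- setdiff(metrics, names(records))
  if (length(missing_cols))
    stop_lotqa("lotqa_configuration_error", "missing metric column(s): %s",
               paste(missing_cols, collapse = ", "))
  sites <- sort(unique(records$site))
  rows <- list()
  for (m in metrics) {
    all_vals <- records[[m]][is.finite(records[[m]])]
    for (s in sites) {
      sv <- records[[m]][records$site == s]
      sv <- sv[is.finite(sv)]
      if (length(sv) < 2) {
        warning(sprintf("site '%s' has < 2 values for %s; skipped", s, m),
                call. = FALSE)
        next
      }
      w <- tryCatch(welch_t(sv, all_vals),
                    lotqa_undefined_statistic_error = function(e) {
                      warning(sprintf("site '%s', metric %s: %s; skipped",
                                      s, m, conditionMessage(e)), call. = FALSE)
                      NULL
                    })
      if (is.null(w)) next
      rows[[length(rows) + 1L]] <-
        data.frame(site = s, metric = m, n_site = length(sv),
                   n_all = length(all_vals), t_statistic = w$t_statistic,
                   df = w$df, p_value = w$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(site = character(), metric = character(),
                      n_site = integer(), n_all = integer(),
                      t_statistic = numeric(), df = numeric(),
                      p_value = numeric())
  if (p_adjust != "none")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Flag fractions where detector signal and attainment co-decline
#'
#' Robust per-plan trend screen: a fraction is flagged when both the
#' detector signal and the attainment rate fall below
#' \code{median - z * MAD} of their own series (MAD with the usual 1.4826
#' normal-consistency constant). Both conditions are required, so an
#' attainment dip without an exit-signal dip (or vice versa) is not
#' flagged.
#'
#' @param records Data.frame for a single plan with columns
#'   \code{fraction}, \code{eta_percent}, \code{detector_signal}.
#' @param signal_threshold_z z-threshold for the detector signal.
#' @param eta_threshold_z z-threshold for the attainment rate.
#' @return Sorted integer vector of flagged fraction numbers.
#' @export
fraction_trend <- function(records, signal_threshold_z = 3,
                           eta_threshold_z = 3) {
  if (!all(c("fraction", "eta_percent", "detector_signal") %in% names(records)))
    stop_lotqa("lotqa_configuration_error",
               "records need fraction, eta_percent and detector_signal columns")
  if ("plan_id" %in% names(records) && length(unique(records$plan_id)) > 1)
    stop_lotqa("lotqa_parameter_error", "fraction_trend expects a single plan")
  ok <- is.finite(records$eta_percent) & is.finite(records$detector_signal)
  r <- records[ok, , drop = FALSE]
  if (nrow(r) < 3)
    stop_lotqa("lotqa_insufficient_data_error",
               "need >= 3 fractions with both signal and attainment")
  med_s <- stats::median(r$detector_signal)
  mad_s <- stats::mad(r$detector_signal)
  med_e <- stats::median(r$eta_percent)
  mad_e <- stats::mad(r$eta_percent)
  flag <- r$detector_signal < med_s - signal_threshold_z * mad_s &
    r$eta_percent < med_e - eta_threshold_z * mad_e
  sort(as.integer(r$fraction[flag]))
}
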