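# Brute-force oracles and tiny fixture builders, deliberately written as
# naive loops independent of the package's vectorized paths.

planned_from_matrix <- function(m, dur, plan_id = "p1", site = "prostate") {
  lotqa:::new_planned_sinogram(plan_id, site, m, dur)
}

measured_from_matrix <- function(m, dur, plan_id = "p1", fraction = 1L,
                                 resolution = NA_real_, signal = 1.0) {
  structure(list(plan_id = plan_id, site = "prostate",
                 fraction_index = as.integer(fraction), lot_ms = m,
                 projection_duration_ms = dur,
                 sensor_resolution_ms = resolution,
                 detector_signal = signal),
            class = "measured_sinogram")
}

# Event-level zero-bin count: |measured - planned| <= w/2 over planned-open
# cells, by explicit double loop.
oracle_zero_count <- function(p, m, w) {
  cnt <- 0L
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0 && abs(m[i, j] - p[i, j]) <= w / 2) cnt <- cnt + 1L
  }
  cnt
}

oracle_rank <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }
  r
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# All permutations of a vector, by recursive insertion (list of vectors).
oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  rho <- oracle_pearson(rx, ry)
  rhos <- vapply(oracle_perms(ry), function(pp) oracle_pearson(rx, pp), 0)
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

oracle_welch <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Random small sinogram pair for oracle-equivalence sweeps.
random_sinogram_pair <- function(seed) {
  withr::with_seed(seed, {
    nr <- sample(2:10, 1); nc <- sample(2:10, 1)
    dur <- 500
    p <- matrix(0, nr, nc)
    open <- matrix(runif(nr * nc) < 0.6, nr, nc)
    p[open] <- runif(sum(open), 1, dur)
    if (!any(p > 0)) p[1, 1] <- 100
    m <- p
    idx <- which(p > 0)
    m[idx] <- pmax(0, p[idx] + rnorm(length(idx), 0, 4))
    list(p = p, m = m, dur = dur)
  })
}
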