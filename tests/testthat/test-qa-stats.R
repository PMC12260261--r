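session_df <- function(eta, plan = "p1", site = "prostate",
                       frac = seq_along(eta)) {
  data.frame(plan_id = plan, site = site, fraction = frac,
             eta_percent = eta, stringsAsFactors = FALSE)
}

test_that("group summaries report pooled mean, sample SD and IQR", {
  s <- summarize_sessions(session_df(c(95, 95, 95)), "all")
  expect_equal(s$mean, 95)
  expect_equal(s$sd, 0)
  expect_equal(s$iqr, 0)
  expect_equal(nrow(s$outliers[[1]]), 0L)

  vals <- c(90, 94, 95, 96, 99)
  s2 <- summarize_sessions(session_df(vals), "all")
  expect_equal(s2$mean, 94.8)
  # two-pass sample SD evaluated independently
  expect_equal(s2$sd, sqrt(sum((vals - mean(vals))^2) / 4), tolerance = 1e-12)

  two <- rbind(session_df(c(95, 96, 94), site = "head"),
               session_df(c(91, 92), site = "pelvis"))
  s3 <- summarize_sessions(two, "site")
  expect_equal(s3$group_label, c("head", "pelvis"))
  expect_equal(s3$n, c(3L, 2L))
})

test_that("single-value groups warn and report SD 0", {
  expect_warning(s <- summarize_sessions(session_df(97), "all"), "single")
  expect_equal(s$sd, 0)
})

test_that("summaries are invariant to record order", {
  df <- rbind(session_df(c(95, 70, 96, 97, 94, 98), site = "head"),
              session_df(c(91, 92, 93), site = "pelvis", plan = "p2"))
  a <- summarize_sessions(df, "site")
  b <- summarize_sessions(df[sample(nrow(df)), ], "site")
  expect_equal(a$mean, b$mean)
  expect_equal(a$sd, b$sd)
  expect_equal(a$iqr, b$iqr)
  expect_equal(lapply(a$outliers, function(o) sort(o$eta_percent)),
               lapply(b$outliers, function(o) sort(o$eta_percent)))
})

test_that("IQR fences flag exactly the values strictly outside", {
  r <- iqr_outliers(c(1, 2, 3, 4))
  expect_equal(length(r$outliers), 0L)

  v <- c(10, 94, 95, 95, 96, 96, 97)
  r2 <- iqr_outliers(v)
  expect_equal(r2$outliers, 1L)
  expect_true(r2$low_side)
  # fences recomputed by hand from type-7 quartiles
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(r2$fences, c(q[1] - 1.5 * (q[2] - q[1]),
                            q[2] + 1.5 * (q[2] - q[1])))

  r3 <- iqr_outliers(rep(5, 6))
  expect_equal(r3$iqr, 0)
  expect_equal(length(r3$outliers), 0L)
  expect_error(iqr_outliers(c(1, 2, 3)),
               class = "lotqa_insufficient_data_error")
})

test_that("flagged outliers always lie outside the fences on random data", {
  for (s in 1:20) {
    v <- withr::with_seed(s, c(rnorm(12, 95, 1), runif(2, 50, 150)))
    r <- iqr_outliers(v)
    expect_true(all(v[r$outliers] < r$fences[1] | v[r$outliers] > r$fences[2]))
    inside <- setdiff(seq_along(v), r$outliers)
    expect_true(all(v[inside] >= r$fences[1] & v[inside] <= r$fences[2]))
  }
})

test_that("correlation strength follows the five-level cutpoints", {
  expect_equal(classify_correlation(0.1), "very_weak")
  expect_equal(classify_correlation(0.2), "weak")
  expect_equal(classify_correlation(-0.39), "weak")
  expect_equal(classify_correlation(0.4), "moderate")
  expect_equal(classify_correlation(0.43), "moderate")
  expect_equal(classify_correlation(0.6), "strong")
  expect_equal(classify_correlation(-0.79), "strong")
  expect_equal(classify_correlation(0.8), "very_strong")
  expect_equal(classify_correlation(-1), "very_strong")
  expect_error(classify_correlation(1.5), class = "lotqa_parameter_error")
})

test_that("monotone data gives rho 1 and very_strong", {
  r <- spearman_cor(1:8, (1:8)^3)
  expect_equal(r$rho, 1)
  expect_equal(r$strength, "very_strong")
})

test_that("spearman matches brute-force rank Pearson and permutation p", {
  for (s in 1:8) {
    xy <- withr::with_seed(s, list(x = rnorm(6), y = rnorm(6)))
    got <- spearman_cor(xy$x, xy$y)
    want <- oracle_spearman(xy$x, xy$y)
    expect_equal(got$rho, want$rho, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  # ties handled by average ranks
  x <- c(1, 1, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 6)
  got <- spearman_cor(x, y)
  want <- oracle_spearman(x, y)
  expect_equal(got$rho, want$rho, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)
  expect_equal(got$rho, unname(stats::cor(x, y, method = "spearman")),
               tolerance = 1e-12)
})

test_that("large-n spearman p uses the t approximation", {
  xy <- withr::with_seed(4, list(x = rnorm(30), y = rnorm(30)))
  got <- spearman_cor(xy$x, xy$y)
  tt <- got$rho * sqrt(28 / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * stats::pt(-abs(tt), 28), tolerance = 1e-12)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_cor(c(1, 1, 1, 1), c(1, 2, 3, 4)),
               class = "lotqa_undefined_statistic_error")
  expect_error(spearman_cor(1:2, 1:2), class = "lotqa_insufficient_data_error")
  expect_error(spearman_cor(1:4, 1:5), class = "lotqa_parameter_error")
})

test_that("welch test matches the closed-form formulas and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- welch_t(a, b)
  want <- oracle_welch(a, b)
  expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
  expect_equal(got$df, want$df, tolerance = 1e-10)
  expect_equal(got$p_value, want$p, tolerance = 1e-10)

  for (s in 1:6) {
    ab <- withr::with_seed(100 + s, list(a = rnorm(5, 1), b = rnorm(7)))
    got <- welch_t(ab$a, ab$b)
    want <- oracle_welch(ab$a, ab$b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    rev <- welch_t(ab$b, ab$a)
    expect_equal(rev$t_statistic, -got$t_statistic)
    expect_equal(rev$p_value, got$p_value)
  }

  same <- welch_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(c(2, 2), c(2, 2)),
               class = "lotqa_undefined_statistic_error")
})

test_that("site-vs-pool tests separate a shifted site and keep cardinality", {
  df <- withr::with_seed(9, rbind(
    session_df(rnorm(20, 95, 1), site = "prostate"),
    session_df(rnorm(20, 95, 1), site = "head", plan = "p2"),
    session_df(rnorm(20, 75, 1), site = "sbrt", plan = "p3")))
  tab <- site_vs_all_tests(df)
  expect_equal(nrow(tab), 3L)
  expect_lt(tab$p_value[tab$site == "sbrt"], 1e-6)
  # fixed instance agrees with welch_t directly
  direct <- welch_t(df$eta_percent[df$site == "head"], df$eta_percent)
  expect_equal(tab$p_value[tab$site == "head"], direct$p_value)
  expect_error(site_vs_all_tests(df, metrics = "nope"),
               class = "lotqa_configuration_error")
  expect_warning(site_vs_all_tests(rbind(df, session_df(95, site = "pelvis",
                                                        plan = "p4"))),
                 "pelvis")
})

test_that("trend flags need both detector and attainment dips", {
  flat <- data.frame(plan_id = "p", fraction = 1:6,
                     eta_percent = c(95, 95.1, 94.9, 95, 95.05, 94.95),
                     detector_signal = c(1, 1.001, 0.999, 1, 1.0005, 0.9995))
  expect_equal(fraction_trend(flat), integer())

  eta_only <- flat
  eta_only$eta_percent[4] <- 60
  expect_equal(fraction_trend(eta_only), integer())

  both <- eta_only
  both$detector_signal[4] <- 0.9
  expect_equal(fraction_trend(both), 4L)

  expect_error(fraction_trend(flat[, c("plan_id", "fraction", "eta_percent")]),
               class = "lotqa_configuration_error")
  expect_error(fraction_trend(flat[1:2, ]),
               class = "lotqa_insufficient_data_error")
})

test_that("the co-decline scenario is flagged end to end", {
  tr <- simulate_trend_scenario(
    archetype_parameters("prostate", beam_on_time_s = 60),
    error_model(latency_sd_ms = 0.2, jitter_sd_ms = 1, drop_probability = 0.001),
    n_fractions = 10, anomaly_fractions = c(3, 5), anomaly_depth = 0.1,
    noise_sd = 0.01, seed = 11)
  expect_equal(fraction_trend(tr), c(3L, 5L))
})
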