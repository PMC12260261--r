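test_that("plan geometry follows beam-on time and gantry period", {
  p <- archetype_parameters("sbrt")
  expect_equal(n_projections_of(p), 693L)
  expect_equal(projection_duration_ms_of(p), 33.18 / 51 * 1000, tolerance = 1e-12)
  plan <- generate_plan(p, seed = 4)
  expect_equal(dim(plan$lot_ms), c(693L, 64L))
  expect_true(all(plan$lot_ms >= 0))
  expect_true(all(plan$lot_ms <= plan$projection_duration_ms))
})

test_that("invalid plan parameters are rejected", {
  expect_error(plan_parameters("x", "sbrt", modulation_factor = 0.9),
               class = "lotqa_parameter_error")
  expect_error(plan_parameters("x", "sbrt", beam_on_time_s = 1e-6,
                               gantry_period_s = 30),
               class = "lotqa_parameter_error")
  expect_error(archetype_parameters("liver"), class = "lotqa_parameter_error")
})

test_that("openings stay inside the open leaf band", {
  p <- archetype_parameters("head", open_leaf_band = c(20L, 30L))
  plan <- generate_plan(p, seed = 2)
  open_cols <- which(colSums(plan$lot_ms > 0) > 0)
  expect_true(all(open_cols >= 21 & open_cols <= 31))
})

test_that("realized modulation factor matches the request for every site", {
  for (site in site_archetypes()$site) {
    plan <- generate_plan(archetype_parameters(site), seed = 9)
    mf <- realized_modulation_factor(plan)
    req <- site_archetypes()$modulation_factor[site_archetypes()$site == site]
    expect_lt(abs(mf / req - 1), 0.10)
  }
})

test_that("modulation factor 1 forces all openings equal", {
  plan <- generate_plan(archetype_parameters("prostate", modulation_factor = 1),
                        seed = 3)
  v <- plan$lot_ms[plan$lot_ms > 0]
  expect_true(length(v) > 0)
  expect_equal(max(v), min(v))
  expect_equal(realized_modulation_factor(plan), 1)
})

test_that("plan generation is seed-deterministic", {
  p <- archetype_parameters("pelvis")
  a <- generate_plan(p, seed = 1)
  b <- generate_plan(p, seed = 1)
  c <- generate_plan(p, seed = 2)
  expect_identical(a$lot_ms, b$lot_ms)
  expect_false(identical(a$lot_ms, c$lot_ms))
})

test_that("zero-error model with dividing resolution reproduces the plan", {
  plan <- generate_plan(archetype_parameters("prostate"), seed = 5)
  # force planned LOTs onto the 3 ms sensor grid so quantization is exact
  plan$lot_ms <- lotqa:::quantize_ms(plan$lot_ms, 3)
  m <- apply_error_model(plan, error_model(sensor_resolution_ms = 3), 1)
  expect_identical(m$lot_ms, plan$lot_ms)
})

test_that("pure latency shifts every opening before clamping", {
  dur <- 1000
  p <- planned_from_matrix(matrix(c(0, 100, 250, 400), 2, 2), dur)
  m <- apply_error_model(p, error_model(latency_mean_ms = 10,
                                        sensor_resolution_ms = 1), 1)
  idx <- p$lot_ms > 0
  expect_equal(m$lot_ms[idx], p$lot_ms[idx] + 10)
  expect_true(all(m$lot_ms[!idx] == 0))
})

test_that("measured LOTs are quantized, clamped and shaped like the plan", {
  plan <- generate_plan(archetype_parameters("hn"), seed = 6)
  em <- error_model(latency_mean_ms = 2, latency_sd_ms = 1, jitter_sd_ms = 4,
                    drop_probability = 0.05, sensor_resolution_ms = 3, seed = 8)
  m <- apply_error_model(plan, em, 2)
  expect_equal(dim(m$lot_ms), dim(plan$lot_ms))
  expect_true(all(m$lot_ms >= 0))
  expect_true(all(m$lot_ms <= plan$projection_duration_ms))
  expect_true(all(abs(m$lot_ms / 3 - round(m$lot_ms / 3)) < 1e-9))
  expect_true(all(m$lot_ms[plan$lot_ms == 0] == 0))
})

test_that("error model is deterministic per (seed, fraction) and matches its raw draws", {
  plan <- generate_plan(archetype_parameters("chest"), seed = 7)
  em <- error_model(latency_mean_ms = 1, latency_sd_ms = 0.5, jitter_sd_ms = 5,
                    sensor_resolution_ms = 3, seed = 21)
  m1 <- apply_error_model(plan, em, 3)
  m2 <- apply_error_model(plan, em, 3)
  m3 <- apply_error_model(plan, em, 4)
  expect_identical(m1$lot_ms, m2$lot_ms)
  expect_false(identical(m1$lot_ms, m3$lot_ms))

  # independent re-simulation from the same underlying draw stream
  idx <- which(plan$lot_ms > 0)
  d <- lotqa:::error_draws(21, 3, length(idx))
  raw <- plan$lot_ms[idx] + (1 + 0.5 * d$latency_z) + 5 * d$jitter_z
  resid <- raw - plan$lot_ms[idx] - (1 + 0.5 * d$latency_z)
  expect_lt(abs(stats::sd(resid) / 5 - 1), 0.10)  # jitter SD recovered
  dur <- plan$projection_duration_ms
  expected <- pmin(lotqa:::quantize_ms(pmin(pmax(raw, 0), dur), 3),
                   floor(dur / 3) * 3)
  expect_equal(m1$lot_ms[idx], expected)
})

test_that("dropped openings are measured as zero at the configured rate", {
  plan <- generate_plan(archetype_parameters("chest"), seed = 11)
  em <- error_model(drop_probability = 0.2, sensor_resolution_ms = 3, seed = 5)
  m <- apply_error_model(plan, em, 1)
  n <- sum(plan$lot_ms > 0)
  drop_rate <- sum(m$lot_ms[plan$lot_ms > 0] == 0) / n
  expect_lt(abs(drop_rate - 0.2), 0.03)
})

test_that("cohort cardinalities follow the spec list", {
  em <- error_model(jitter_sd_ms = 1, seed = 1)
  one <- list(list(params = archetype_parameters("head",
                                                 beam_on_time_s = 20),
                   model = em, n_fractions = 3L))
  co <- generate_cohort(one, seed = 2)
  expect_equal(nrow(co$sessions), 3L)
  expect_equal(length(co$measured), 3L)

  specs <- list()
  for (site in site_archetypes()$site) {
    for (k in 1:2) {
      pp <- archetype_parameters(site, plan_id = sprintf("%s_%d", site, k),
                                 beam_on_time_s = 15)
      specs[[length(specs) + 1L]] <- list(params = pp, model = em,
                                          n_fractions = 5L)
    }
  }
  co2 <- generate_cohort(specs, seed = 3)
  expect_equal(nrow(co2$sessions), 60L)
  expect_equal(as.vector(table(co2$sessions$site)), rep(10L, 6))
  expect_error(generate_cohort(list(), 1), class = "lotqa_parameter_error")
})

test_that("mean attainment decreases as the error scale grows", {
  pp <- archetype_parameters("prostate", beam_on_time_s = 60)
  etas <- vapply(c(0.5, 3, 8), function(j) {
    em <- error_model(jitter_sd_ms = j, sensor_resolution_ms = 3, seed = 13)
    co <- generate_cohort(list(list(params = pp, model = em,
                                    n_fractions = 2L)), seed = 4)
    mean(co$sessions$eta_percent)
  }, 0)
  expect_true(all(diff(etas) < 0))
})

test_that("detector trend baseline and anomalies behave as constructed", {
  flat <- generate_detector_trend(8, seed = 3)
  expect_true(all(abs(flat - 1) < 0.05))
  tr <- generate_detector_trend(8, anomaly_fractions = c(3, 5),
                                anomaly_depth = 0.1, noise_sd = 0.01, seed = 3)
  expect_equal(tr[c(3, 5)], flat[c(3, 5)] * 0.9)
  expect_equal(tr[-c(3, 5)], flat[-c(3, 5)])
  expect_error(generate_detector_trend(5, anomaly_fractions = 9),
               class = "lotqa_parameter_error")
})

test_that("synthetic gamma pass rates correlate with attainment", {
  em <- error_model(latency_sd_ms = 2, jitter_sd_ms = 2, seed = 2)
  pp <- archetype_parameters("pelvis", beam_on_time_s = 30)
  co <- generate_cohort(list(list(params = pp, model = em,
                                  n_fractions = 20L)),
                        seed = 6, gamma_model = list(a = 0.5, noise_sd = 0.1))
  r <- spearman_cor(co$sessions$eta_percent, co$sessions$gamma_delta4)
  expect_gt(r$rho, 0.5)
})
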