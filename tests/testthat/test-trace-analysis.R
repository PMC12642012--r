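test_that("moving average: constants, identity, and centered linearity", {
  tt <- seq(0, 10, by = 0.1)
  expect_equal(moving_average(rep(7, length(tt)), tt, 5), rep(7, length(tt)))
  x <- sin(tt)
  expect_identical(moving_average(x, tt, 0), x)
  # linear ramp is invariant under a centered mean away from the edges
  ramp <- 2 * tt + 1
  sm <- moving_average(ramp, tt, 1)
  interior <- tt >= 1 & tt <= 9
  expect_equal(sm[interior], ramp[interior], tolerance = 1e-9)
  expect_length(moving_average(numeric(0), numeric(0), 5), 0L)
})

test_that("an arrest-flat trace yields zero beats", {
  tr <- simulate_lv_trace(trace_spec(beating = FALSE, edp_mmhg = 8,
                                     duration_s = 30, seed = 11))
  b <- detect_beats(tr)
  expect_s3_class(b, "beat_series")
  expect_equal(nrow(b), 0L)
  expect_false(classify_beating(b))
})

test_that("beat count matches simulator truth at 4 pulses per second", {
  tr <- simulate_lv_trace(trace_spec(hr_bpm = 240, sys_peak_mmhg = 78,
                                     edp_mmhg = 8, noise_sd_mmhg = 1,
                                     hr_jitter_frac = 0, seed = 3))
  truth <- attr(tr, "truth")
  b <- detect_beats(tr)
  expect_lte(abs(nrow(b) - truth$n_beats), 1L)
})

test_that("a symmetric 3-sample peak is refined to the middle sample", {
  b <- detect_beats(sampled_trace(0:2, c(0, 1, 0)),
                    min_prominence_mmhg = 0.5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$peak_time, 1, tolerance = 1e-9)
  expect_equal(b$peak_pressure, 1, tolerance = 1e-9)
  expect_equal(b$trough_pressure, 0, tolerance = 1e-9)
})

test_that("parabola refinement recovers off-grid peak times", {
  # noiseless quadratic bumps whose true apex lies between samples;
  # oracle: argmax of the analytic pulse on a dense resampling
  for (frac in c(0.17, 0.5, 0.83)) {
    t_true <- 40 + frac
    tt <- 0:80
    y <- pmax(0, 30 - 2 * (tt - t_true)^2)
    b <- detect_beats(sampled_trace(tt, y), min_prominence_mmhg = 10)
    dense <- seq(39, 42, by = 1e-4)
    oracle <- dense[which.max(pmax(0, 30 - 2 * (dense - t_true)^2))]
    expect_equal(nrow(b), 1L)
    expect_lt(abs(b$peak_time - oracle), 0.1)
  }
})

test_that("heart rate follows the mean inter-peak interval", {
  beats <- structure(data.frame(peak_time = seq(0, 10, by = 0.25)),
                     class = c("beat_series", "data.frame"))
  expect_equal(heart_rate(beats), 240)
  one <- structure(data.frame(peak_time = 1), class = c("beat_series",
                                                        "data.frame"))
  expect_equal(heart_rate(one), 0)
})

test_that("developed pressure averages peak-trough excursions", {
  beats <- structure(data.frame(peak_time = c(1, 2), peak_pressure = c(80, 80),
                                trough_pressure = c(8, 8)),
                     class = c("beat_series", "data.frame"))
  expect_equal(developed_pressure(beats), 72)
  single <- beats[1, ]
  expect_equal(developed_pressure(single), 72)
  none <- beats[0, ]
  expect_true(is.na(developed_pressure(none)))
})

test_that("dP/dt of a pure sinusoid matches the analytic derivative", {
  tt <- seq(0, 10, by = 0.001)
  A <- 30; f <- 2
  tr <- sampled_trace(tt, 50 + A * sin(2 * pi * f * tt))
  b <- detect_beats(tr)
  pd <- pressure_derivatives(tr, b)
  expect_equal(pd$dpdt_max, 2 * pi * f * A, tolerance = 0.01)
  expect_equal(pd$dpdt_min, -2 * pi * f * A, tolerance = 0.01)
})

test_that("time reversal swaps the roles of dP/dt max and min", {
  tr <- simulate_lv_trace(trace_spec(hr_bpm = 180, sys_peak_mmhg = 80,
                                     noise_sd_mmhg = 0, hr_jitter_frac = 0,
                                     duration_s = 20, seed = 5))
  rev_tr <- sampled_trace(tr$times, rev(tr$values))
  pd <- pressure_derivatives(tr, detect_beats(tr))
  pd_rev <- pressure_derivatives(rev_tr, detect_beats(rev_tr))
  expect_equal(pd_rev$dpdt_max, -pd$dpdt_min, tolerance = 0.02)
  expect_equal(pd_rev$dpdt_min, -pd$dpdt_max, tolerance = 0.02)
})

test_that("pressure scaling scales LVDP, dP/dt and AUC but not HR", {
  tr <- simulate_lv_trace(trace_spec(hr_bpm = 200, sys_peak_mmhg = 60,
                                     duration_s = 30, seed = 8))
  sc <- sampled_trace(tr$times, 2.5 * tr$values)
  b1 <- detect_beats(tr)
  b2 <- detect_beats(sc, min_prominence_mmhg = 50)
  expect_equal(heart_rate(b2), heart_rate(b1), tolerance = 1e-3)
  expect_equal(developed_pressure(b2), 2.5 * developed_pressure(b1),
               tolerance = 0.01)
  expect_equal(pt_integral(sc), 2.5 * pt_integral(tr), tolerance = 1e-9)
  pd1 <- pressure_derivatives(tr, b1)
  pd2 <- pressure_derivatives(sc, b2)
  expect_equal(pd2$dpdt_max, 2.5 * pd1$dpdt_max, tolerance = 0.01)
})

test_that("time shifts move beat times but leave metrics unchanged", {
  tr <- simulate_lv_trace(trace_spec(hr_bpm = 200, sys_peak_mmhg = 70,
                                     duration_s = 30, seed = 9))
  shifted <- sampled_trace(tr$times + 100, tr$values)
  b1 <- detect_beats(tr)
  b2 <- detect_beats(shifted)
  expect_equal(b2$peak_time, b1$peak_time + 100, tolerance = 1e-9)
  expect_equal(heart_rate(b2), heart_rate(b1), tolerance = 1e-12)
  expect_equal(developed_pressure(b2), developed_pressure(b1),
               tolerance = 1e-12)
})

test_that("beat detection is stable under small added noise", {
  base <- trace_spec(hr_bpm = 220, sys_peak_mmhg = 78, edp_mmhg = 8,
                     noise_sd_mmhg = 0, hr_jitter_frac = 0,
                     duration_s = 30, seed = 1)
  clean <- simulate_lv_trace(base)
  n_clean <- nrow(detect_beats(clean))
  hr_clean <- heart_rate(detect_beats(clean))
  amp <- 70
  for (s in 1:5) {
    set.seed(s)
    noisy <- sampled_trace(clean$times,
                           clean$values + rnorm(length(clean$values),
                                                0, 0.02 * amp))
    b <- detect_beats(noisy)
    expect_equal(nrow(b), n_clean)
    expect_equal(heart_rate(b), hr_clean, tolerance = 0.01)
  }
})

test_that("pressure-time integral: rectangle, zero trace and span errors", {
  tt <- seq(0, 100, by = 0.5)
  expect_equal(pt_integral(sampled_trace(tt, rep(10, length(tt)))), 1000)
  expect_equal(pt_integral(sampled_trace(tt, rep(0, length(tt)))), 0)
  tr <- sampled_trace(tt, rep(10, length(tt)))
  expect_equal(pt_integral(tr, span = c(10, 30)), 200)
  expect_error(pt_integral(tr, span = c(0, 200)), "extent")
})

test_that("beating classification needs a sustained rhythm", {
  ectopic <- structure(data.frame(peak_time = c(100, 900, 2400)),
                       class = c("beat_series", "data.frame"))
  expect_false(classify_beating(ectopic))
  resus <- simulate_lv_trace(trace_spec(hr_bpm = 226, sys_peak_mmhg = 81,
                                        duration_s = 70, seed = 4))
  expect_true(classify_beating(detect_beats(resus)))
})

test_that("reperfusion summary recovers simulator truth", {
  spec <- trace_spec(hr_bpm = 226, sys_peak_mmhg = 81, edp_mmhg = 8,
                     duration_s = 60, rate_hz = 500, seed = 21)
  lvp <- simulate_lv_trace(spec)
  truth <- attr(lvp, "truth")
  flow <- simulate_flow_trace(6.91, duration_s = 60, seed = 22)
  s <- summarize_reperfusion(lvp, flow, expected_span_s = 60)
  expect_true(s$beating)
  expect_equal(s$hr_bpm, truth$hr_bpm, tolerance = 0.02)
  expect_equal(s$lvdp_mmhg, truth$lvdp_mmhg, tolerance = 0.02)
  expect_equal(s$dpdt_max, truth$dpdt_max, tolerance = 0.02)
  expect_equal(s$cfr_ml_min, 6.91, tolerance = 0.02)
})

test_that("non-beating summary keeps flow but drops kinetic fields", {
  lvp <- simulate_lv_trace(trace_spec(beating = FALSE, duration_s = 30,
                                      seed = 31))
  flow <- simulate_flow_trace(6, noise_sd = 0, duration_s = 30, seed = 32)
  s <- summarize_reperfusion(lvp, flow, expected_span_s = 30)
  expect_false(s$beating)
  expect_true(is.na(s$hr_bpm))
  expect_true(is.na(s$lvdp_mmhg))
  expect_equal(s$cfr_ml_min, 6)
  expect_false(is.na(s$auc))
})

test_that("timepoint table covers each present 10-minute mark", {
  # 25-minute record at low rate: marks A and B only
  spec <- trace_spec(hr_bpm = 180, sys_peak_mmhg = 70, duration_s = 1500,
                     rate_hz = 100, seed = 41)
  lvp <- simulate_lv_trace(spec)
  flow <- simulate_flow_trace(6, duration_s = 1500, rate_hz = 1, seed = 42)
  expect_warning(s <- summarize_reperfusion(lvp, flow), "record covers")
  expect_equal(s$timepoints$label, c("A", "B"))
  expect_equal(s$timepoints$minute, c(10, 20))
  expect_true(all(is.finite(s$timepoints$hr_bpm)))
})

test_that("missing channels are flagged, not fatal", {
  flow <- simulate_flow_trace(6, duration_s = 30, seed = 51)
  s <- summarize_reperfusion(NULL, flow, expected_span_s = 30)
  expect_true("LVP" %in% s$missing)
  expect_equal(s$cfr_ml_min, mean(flow$values))
})
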