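mj_frac_for_test <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

test_that("stationary traces yield no saccades and bad traces error", {
  still <- data.frame(t_ms = 0:1000, x_deg = 0, y_deg = 0)
  expect_equal(nrow(detect_saccades(still)), 0)

  short <- data.frame(t_ms = 0:10, x_deg = 0, y_deg = 0)
  expect_error(detect_saccades(short), "too short")

  uneven <- data.frame(t_ms = c(0:100, 102:200), x_deg = 0, y_deg = 0)
  expect_error(detect_saccades(uneven), "uniform")
})

test_that("Gaussian speed profile crosses thresholds at the analytic times", {
  # speed 400 exp(-(t-150)^2 / (2 15^2)): 30 deg/s crossings at
  # 150 -/+ 15 sqrt(2 ln(400/30))
  tr <- gaussian_speed_trace(peak = 400)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  onset_true <- 150 - 15 * sqrt(2 * log(400 / 30))
  offset_true <- 150 + 15 * sqrt(2 * log(400 / 30))
  expect_lt(abs(ev$onset_ms - onset_true), 1)
  expect_lt(abs(ev$offset_ms - offset_true), 1)
  expect_lt(abs(ev$pv_deg_s / 400 - 1), 0.01)
  expect_true(ev$valid)

  # the 900 deg/s variant is rejected by the blink rule
  tr9 <- gaussian_speed_trace(peak = 900)
  ev9 <- detect_saccades(tr9)
  expect_equal(nrow(ev9), 1)
  expect_false(ev9$valid)
  expect_equal(ev9$reject_reason, "blink")
})

test_that("detection is invariant to time translation and rotation", {
  base <- gaussian_speed_trace(peak = 300)
  ev <- detect_saccades(base)

  shifted <- base
  shifted$t_ms <- shifted$t_ms + 5000
  ev_s <- detect_saccades(shifted)
  expect_equal(ev_s$onset_ms, ev$onset_ms + 5000)
  expect_equal(ev_s$pv_deg_s, ev$pv_deg_s)

  th <- 0.83
  rotated <- base
  rotated$x_deg <- base$x_deg * cos(th)
  rotated$y_deg <- base$x_deg * sin(th)
  ev_r <- detect_saccades(rotated)
  expect_equal(ev_r$onset_ms, ev$onset_ms)
  expect_equal(ev_r$pv_deg_s, ev$pv_deg_s, tolerance = 1e-6)
})

test_that("saccade_metrics computes RT, amplitude and the 8-degree rule", {
  t <- 0:2000
  x <- 10 * mj_frac_for_test((t - 1186) / 40)
  tr <- data.frame(t_ms = t, x_deg = x, y_deg = 0)
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)

  done <- saccade_metrics(ev, tr, target_on = 1000, target_pos = c(10, 0))
  expect_equal(done$rt_ms, done$onset_ms - 1000)
  expect_lt(abs(done$amplitude_deg - 10), 0.2)
  expect_true(done$valid)

  # same movement, target 9 degrees away from the landing point
  off <- saccade_metrics(ev, tr, target_on = 1000, target_pos = c(10, 9))
  expect_false(off$valid)
  expect_equal(off$reject_reason, "off_target")

  expect_error(
    saccade_metrics(ev, tr, target_on = 1900, target_pos = c(10, 0)),
    "argument error")
})

test_that("normalized profiles have 20 points and match analytic velocity", {
  # linear displacement: constant velocity over the event
  t <- 0:300
  v <- ifelse(t >= 100 & t < 150, 200, 0)   # deg/s
  x <- cumsum(v) * 1e-3
  tr <- data.frame(t_ms = t, x_deg = x, y_deg = 0)
  ev <- data.frame(onset_ms = 100, offset_ms = 150, pv_deg_s = 200,
                   rt_ms = NA, amplitude_deg = NA, valid = TRUE,
                   reject_reason = "none")
  pr <- normalize_profile(tr, ev)
  expect_length(pr$frac, 20)
  expect_length(pr$displacement_deg, 20)
  mid <- which(pr$frac == 0.5)
  expect_equal(pr$displacement_deg[mid], 5, tolerance = 0.05)
  expect_true(all(abs(pr$velocity_deg_s[3:18] - 200) < 10))
  expect_true(all(diff(pr$displacement_deg) > -1e-6))

  # minimum-jerk saccade: normalized peak velocity equals the trace PV
  beh <- sample_behavior(generator_params(), "good", eccentricity = 15)
  ev2 <- detect_saccades(beh$eye, blink_threshold = 2000)
  pr2 <- normalize_profile(beh$eye, ev2[1, ])
  expect_length(pr2$frac, 20)
  expect_lt(abs(max(pr2$velocity_deg_s) / beh$pv - 1), 0.01)

  too_short <- ev; too_short$offset_ms <- 105
  expect_error(normalize_profile(tr, too_short), "too short")
})

test_that("session saccade recovery matches the generator ground truth", {
  b <- small_bundle()
  sac <- small_saccades()
  tr <- b$truth$trials
  ok <- sac$valid
  expect_gt(mean(ok), 0.95)
  rt_err <- sac$rt_ms[ok] - tr$rt_ms[ok]
  pv_err <- sac$pv_deg_s[ok] / tr$pv_deg_s[ok] - 1
  amp_err <- sac$amplitude_deg[ok] / tr$amplitude_deg[ok] - 1
  expect_gte(mean(abs(rt_err) <= 2), 0.99)
  expect_gte(mean(abs(pv_err) <= 0.01), 0.99)
  expect_true(all(abs(amp_err) <= 0.02))
})
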