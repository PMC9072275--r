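test_that("calibration recovers exact linear maps and errors on degenerate targets", {
  targets <- c(-8.5, 0, 8.5)
  fit <- calibrate(2 * targets + 1, targets)
  expect_equal(fit$gain, 2)
  expect_equal(fit$offset, 1)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-12)

  fit_id <- calibrate(targets, targets)
  expect_equal(fit_id$gain, 1)
  expect_equal(fit_id$offset, 0, tolerance = 1e-12)

  expect_error(calibrate(c(1, 2, 3), c(0, 0, 0)), "distinct")
})

test_that("noisy calibration gain lands in the least-squares sampling band", {
  targets <- rep(c(-8.5, 0, 8.5), each = 5)
  gains <- vapply(1:100, function(s) {
    set.seed(s)
    calibrate(2 * targets + 1 + rnorm(length(targets), 0, 0.05), targets)$gain
  }, numeric(1))
  expect_true(all(gains > 1.98 & gains < 2.02))
})

test_that("calibrated raw-unit traces recover the same estimate as degree traces", {
  cfg <- clean_config()
  rec <- simulate_recording(6, cfg, seed = 8)
  fit <- calibrate(raw = 1.7 * c(-8.5, 0, 8.5) - 0.3, target_deg = c(-8.5, 0, 8.5))
  raw_trace <- rec$trace
  raw_trace$y <- 1.7 * raw_trace$y - 0.3
  est_raw <- run_vog(raw_trace, rec$schedule, calibration = fit)
  est_deg <- run_vog(rec$trace, rec$schedule)
  expect_equal(est_raw$skew_deg, est_deg$skew_deg, tolerance = 1e-6)
})

test_that("velocity filter is exact on constants and linear ramps", {
  t <- (0:999) / 250
  v0 <- vog_velocity(eye_trace(t, rep(1, 1000)))
  expect_true(all(abs(v0) < 1e-9))
  vr <- vog_velocity(eye_trace(t, t))  # 1 deg/s ramp
  expect_true(all(abs(vr - 1) < 1e-6))
  expect_error(vog_velocity(eye_trace((0:4) / 250, numeric(5))), "shorter")
})

test_that("velocity is masked around blink gaps", {
  t <- (0:999) / 250
  m <- rep(FALSE, 1000); m[400:450] <- TRUE
  v <- vog_velocity(eye_trace(t, t, mask = m))
  expect_true(all(is.na(v[400:450])))
  expect_false(anyNA(v[1:390]))
})

test_that("filtered peak velocity is attenuated but ordered by amplitude", {
  # the 44 ms differentiation window is wider than a small saccade, so the
  # measured peak sits well below the analytic peak of the continuous
  # profile; amplitude (the integral) is what the skew estimate relies on
  peaks <- vapply(c(1.14, 2.28, 4.56), function(a) {
    tr <- trace_with_saccades(1.0, a)
    v <- vog_velocity(tr)
    c(max(abs(v)) / attr(tr, "analytic_peaks"), max(abs(v)))
  }, numeric(2))
  expect_true(all(peaks[1, ] > 0.25 & peaks[1, ] < 1))
  expect_true(all(diff(peaks[2, ]) > 0))      # main-sequence ordering survives
  expect_true(all(peaks[2, ] > 10))           # still clears the detector floor
})

test_that("saccade detection: clean events found, amplitudes right, noise rejected", {
  tr <- trace_with_saccades(1.0, 2.28)
  s <- detect_saccades(tr, vog_velocity(tr))
  expect_equal(nrow(s), 1)
  expect_gt(s$amplitude_deg, 2.23)
  expect_lt(s$amplitude_deg, 2.33)

  tr2 <- trace_with_saccades(c(1.0, 1.3), c(2.28, -2.28))
  s2 <- detect_saccades(tr2, vog_velocity(tr2))
  expect_equal(nrow(s2), 2)
  expect_true(all(diff(s2$onset_s) > 0))
  expect_equal(sign(s2$amplitude_deg), c(1, -1))

  # pure-noise false positive rate
  empty <- vapply(1:200, function(s) {
    set.seed(s)
    t <- (0:2499) / 250
    tr <- eye_trace(t, rnorm(2500, 0, 0.05))
    nrow(detect_saccades(tr, vog_velocity(tr))) == 0
  }, logical(1))
  expect_gte(mean(empty), 0.95)
})

test_that("event skew integrates the saccade inside the -0.5/+1.5 s window", {
  tr <- trace_with_saccades(2.18, -1.14, duration_s = 5)  # switch at 2, onset +0.18
  v <- vog_velocity(tr)
  s <- detect_saccades(tr, v)
  ev <- event_skew(tr, v, s, switch_time = 2)
  expect_true(ev$valid)
  expect_equal(ev$exclusion_reason, "none")
  expect_equal(ev$skew_deg_signed, -1.14, tolerance = 0.02)

  # no saccade in window -> zero with reason
  ev0 <- event_skew(tr, v, s, switch_time = 4.0)
  expect_true(ev0$valid)
  expect_equal(ev0$skew_deg_signed, 0)
  expect_equal(ev0$exclusion_reason, "no_saccade")

  # saccade entirely beyond +1.5 s is outside the window
  tr2 <- trace_with_saccades(3.8, 1.14, duration_s = 6)
  v2 <- vog_velocity(tr2)
  s2 <- detect_saccades(tr2, v2)
  ev2 <- event_skew(tr2, v2, s2, switch_time = 2)
  expect_equal(ev2$skew_deg_signed, 0)
  expect_equal(ev2$exclusion_reason, "no_saccade")
})

test_that("a blink gap overlapping the integration span invalidates the event", {
  tr <- trace_with_saccades(2.18, -1.14, duration_s = 5)
  tr$mask[round(2.19 * 250):round(2.21 * 250)] <- TRUE
  v <- vog_velocity(tr)
  s <- detect_saccades(tr, v)
  ev <- event_skew(tr, v, s, switch_time = 2)
  expect_false(ev$valid)
  expect_equal(ev$exclusion_reason, "blink_gap")
})

test_that("no sample outside the event window contributes to the integral", {
  # two saccades: one inside the window, one after it; the window-clipped
  # integral must equal the inside saccade alone
  tr <- trace_with_saccades(c(2.2, 3.8), c(1.14, 1.14), duration_s = 6)
  v <- vog_velocity(tr)
  s <- detect_saccades(tr, v)
  ev <- event_skew(tr, v, s, switch_time = 2)
  expect_equal(ev$skew_deg_signed, 1.14, tolerance = 0.03)
})

test_that("event aggregation rectifies, fences outliers and takes the median", {
  sch <- cover_schedule(c(1, 3, 5, 7, 9), rep(c("left", "right"), length.out = 5))
  mk_ev <- function(sw, val) {
    structure(list(switch_time_s = sw, window_lo = sw - 0.5, window_hi = sw + 1.5,
                   saccades = data.frame(), skew_deg_signed = val, valid = TRUE,
                   exclusion_reason = "none", clipped = FALSE),
              class = "event_skew")
  }
  signs <- c(1, -1, 1, -1, 1)
  ev_const <- Map(mk_ev, c(1, 3, 5, 7, 9), 2.28 * signs)
  est <- estimate_skew(ev_const, sch)
  expect_equal(est$skew_deg, 2.28)
  expect_equal(est$n_events_used, 5)

  ev_out <- Map(mk_ev, c(1, 3, 5, 7, 9), c(2.3, 2.2, 2.4, 9.0, 2.3) * signs)
  est2 <- estimate_skew(ev_out, sch)
  expect_equal(est2$n_events_used, 4)
  expect_equal(est2$skew_deg, 2.3)
  expect_equal(est2$events$exclusion_reason[4], "outlier")

  expect_warning(est0 <- estimate_skew(list(), sch), "no valid")
  expect_equal(est0$skew_deg, 0)
  expect_equal(est0$n_events_used, 0)
})

test_that("velocity integral equals net displacement on simulated clean events", {
  # fundamental-theorem property: area under the velocity curve over the
  # saccade span reproduces the position step
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    amp <- sample(c(-1, 1), 1) * runif(1, 0.5, 5.7)
    onset <- runif(1, 1.0, 1.4)
    tr <- trace_with_saccades(onset, amp)
    v <- vog_velocity(tr)
    sac <- detect_saccades(tr, v)
    ev <- event_skew(tr, v, sac, switch_time = 1.0)
    abs(ev$skew_deg_signed - amp)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("full pipeline is deterministic and accurate on simulated recordings", {
  cfg <- clean_config()
  rec <- simulate_recording(6, cfg, seed = 77)
  est <- run_vog(rec$trace, rec$schedule)
  expect_gt(est$skew_pd, 5.9)
  expect_lt(est$skew_pd, 6.1)
  est2 <- run_vog(rec$trace, rec$schedule)
  expect_identical(est, est2)

  # flat noise-only recording stays near zero
  set.seed(4)
  t <- (0:2499) / 250
  tr <- eye_trace(t, rnorm(2500, 0, 0.05))
  sch <- cover_schedule(c(0.5, 2.5, 4.5, 6.5, 8.5),
                        rep(c("left", "right"), length.out = 5))
  est0 <- run_vog(tr, sch)
  expect_lt(est0$skew_pd, 0.3)
})
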