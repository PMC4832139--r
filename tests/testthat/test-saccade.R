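test_that("interpolate_blinks fills short gaps linearly and leaves long or
           edge gaps invalid", {
  # one 100 ms (6-sample) gap between x = 0 and x = 1
  x <- c(rep(0, 10), rep(NA, 6), rep(1, 10))
  tr <- make_trace(ifelse(is.na(x), 0, x), valid = !is.na(x))
  out <- interpolate_blinks(tr)
  filled <- out$x[11:16]
  expect_true(all(out$valid[11:16]))
  expect_true(all(out$interpolated[11:16]))
  expect_true(all(filled > 0 & filled < 1))
  expect_true(all(abs(diff(out$x[10:17]) - diff(out$x[10:17])[1]) < 1e-12))

  # fully valid trace returned unchanged (plus the flag column)
  tr2 <- make_fixation_trace(20, sd = 0.1, seed = 1)
  out2 <- interpolate_blinks(tr2)
  expect_equal(out2$x, tr2$x)
  expect_false(any(out2$interpolated))

  # a 500 ms gap stays invalid
  valid3 <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 10))
  tr3 <- make_trace(rep(0, 50), valid = valid3)
  out3 <- interpolate_blinks(tr3)
  expect_false(any(out3$valid[11:40]))

  expect_error(interpolate_blinks(make_trace(0:5, valid = rep(FALSE, 6))),
               "no valid samples")
})

test_that("acceleration_series is the magnitude of the forward second
           difference", {
  expect_equal(acceleration_series(make_trace(rep(1, 10)))[1:8], rep(0, 8))

  ramp <- make_trace(seq(0, 3, length.out = 10))   # constant velocity
  expect_equal(acceleration_series(ramp)[1:8], rep(0, 8))

  # injected ballistic movement: compare against an explicit finite
  # difference computed here (independent arithmetic oracle)
  tr <- make_trace(rep(0, 30), rep(0, 30))
  tr <- inject_movement(tr, 15, 4, 3)
  acc <- acceleration_series(tr)
  rate <- 60
  vx <- diff(tr$x) * rate; vy <- diff(tr$y) * rate
  oracle <- sqrt(diff(vx)^2 + diff(vy)^2) * rate
  expect_equal(acc[1:28], oracle)
  burst <- which(acc > 1e-9)
  expect_true(all(diff(burst) == 1))        # single contiguous burst
  # largest finite difference is the landing deceleration: the movement
  # covers the last 5/9 of the 5-degree amplitude in its final sample
  expect_equal(max(acc, na.rm = TRUE), 5 * (5 / 9) * rate^2)

  expect_error(acceleration_series(make_trace(c(0, 1))), "3 samples")
})

test_that("adaptive_threshold is mean + population SD over the 2 s window", {
  # constant acceleration c: SD = 0, threshold = c
  tt <- seq(0, 1999, by = 1000 / 60)
  expect_equal(adaptive_threshold(rep(3.5, length(tt)), tt, 2000), 3.5)

  # {0,0,0,4}: mean 1, population SD sqrt(3) (tests the SD convention)
  expect_equal(adaptive_threshold(c(0, 0, 0, 4), c(0, 500, 1000, 1500), 2000),
               1 + sqrt(3))

  expect_error(adaptive_threshold(c(1, 2), c(0, 100), 5000), "empty")

  # mostly-invalid window flags the trial (NA)
  acc <- rep(1, length(tt)); acc[1:100] <- NA
  expect_true(is.na(adaptive_threshold(acc, tt, 2000)))
})

test_that("classify_saccade partitions latencies at 25/150/250 ms", {
  expect_equal(classify_saccade(100), "express")
  expect_equal(classify_saccade(200), "regular")
  expect_equal(classify_saccade(10), "unclassified")
  expect_equal(classify_saccade(25), "express")
  expect_equal(classify_saccade(150), "regular")
  expect_equal(classify_saccade(250), "regular")
  expect_equal(classify_saccade(250.1), "unclassified")
  # partition: every latency gets exactly one class
  lat <- seq(0, 400, by = 0.5)
  k <- classify_saccade(lat)
  expect_true(all(k %in% c("express", "regular", "unclassified")))
  expect_equal(sum(k == "express") + sum(k == "regular") +
                 sum(k == "unclassified"), length(lat))
})

test_that("detect_target_saccades finds injected movements and applies the
           direction cone", {
  n <- 400
  t_disp <- 200 * DT_MS                      # displacement at ~3333 ms
  disp <- make_disp_row(t_disp, pre = c(5, 5), post = c(7, 5), v = c(0, -18))

  base <- make_fixation_trace(n, sd = 0.02, seed = 31)
  k_on <- 200 + 6                 # first moving sample ~83 ms after t_disp
  tgt_t <- (k_on - 1) * DT_MS
  tgt <- c(disp$post_x + disp$vx * (tgt_t - t_disp) / 1000,
           disp$post_y + disp$vy * (tgt_t - t_disp) / 1000)
  tr <- inject_movement(base, k_on, tgt[1], tgt[2])
  ev <- detect_target_saccades(tr, disp)
  hit <- ev[abs(ev$onset_ms - tgt_t) <= 3 * DT_MS, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$klass, "express")
  expect_lte(hit$deviation_deg, 22.5)
  # forward differencing anticipates the onset by 1-2 samples
  expect_true(hit$latency_ms >= 3 * DT_MS - 1e-9 &&
                hit$latency_ms <= 5 * DT_MS + 1e-9)

  # same movement but 30 degrees off the eye-to-target line: the injected
  # burst yields no event (only unrelated jitter noise could)
  ang <- atan2(tgt[2] - base$y[k_on - 1], tgt[1] - base$x[k_on - 1])
  d <- sqrt(sum((tgt - c(base$x[k_on - 1], base$y[k_on - 1]))^2))
  off <- c(base$x[k_on - 1] + d * cos(ang + 30 * pi / 180),
           base$y[k_on - 1] + d * sin(ang + 30 * pi / 180))
  tr_off <- inject_movement(base, k_on, off[1], off[2])
  ev_off <- detect_target_saccades(tr_off, disp)
  # no accepted event moves along the off-target direction
  off_deg <- (ang + 30 * pi / 180) * 180 / pi
  ddiff <- abs(((ev_off$direction_deg - off_deg + 180) %% 360) - 180)
  expect_false(any(ddiff < 5))

  # perfectly flat trace: zero threshold, no strictly-positive acceleration
  flat <- make_trace(rep(0, n))
  expect_equal(nrow(detect_target_saccades(flat, disp)), 0)
})

test_that("session-level detection recovers injected ground-truth events
           with the correct class", {
  obs <- observer_config(p_express = 0.45, p_regular = 0.45, p_press = 0.3,
                         blink_rate = 0)
  pipe <- run_synthetic_pipeline(120, obs, seed = 33)
  gt <- pipe$resp$ground_truth
  t0 <- pipe$stim$displacements$time_ms
  sac <- pipe$det$saccades

  margin <- 2 * DT_MS
  for (i in seq_len(nrow(gt))) {
    e_lat <- gt$express_onset_ms[i] - t0[i]
    if (isTRUE(gt$express[i]) && e_lat >= 25 + margin && e_lat < 150 - margin)
      expect_true(any(sac$trial_id == gt$trial_id[i] &
                        sac$klass == "express"))
    r_lat <- gt$regular_onset_ms[i] - t0[i]
    if (isTRUE(gt$regular[i]) && r_lat >= 150 + margin &&
        r_lat <= 250 - margin)
      expect_true(any(sac$trial_id == gt$trial_id[i] &
                        sac$klass == "regular"))
  }
  # hard invariant: every accepted event satisfies the cone
  expect_true(all(sac$deviation_deg <= 22.5))
})

test_that("pre_post_saccade_counts separates a responsive observer from
           chance and flags the degenerate case", {
  obs <- observer_config(p_express = 0.6, p_regular = 0.6, p_press = 0,
                         blink_rate = 0)
  pipe <- run_synthetic_pipeline(80, obs, seed = 35)
  res <- pre_post_saccade_counts(pipe$resp$gaze, pipe$stim$displacements)
  expect_gt(res$t_test$t, 0)
  expect_lt(res$t_test$p, 0.05)
  expect_gt(sum(res$post), sum(res$pre))

  # no movement at all: zero counts everywhere, flagged t
  stim <- run_session(scene_config(), n_trials = 5, seed = 36,
                      store_tracks = FALSE)
  flat_gaze <- data.frame(
    time_ms = seq(0, stim$duration_ms, by = DT_MS))
  flat_gaze$x <- 0; flat_gaze$y <- 0; flat_gaze$valid <- TRUE
  res0 <- pre_post_saccade_counts(flat_gaze, stim$displacements)
  expect_equal(res0$t_test$flag, "zero_variance")
})

test_that("pre/post counts are symmetric under a saccade-free noise trace", {
  # null calibration: with pure jitter the paired t should rarely reject
  pvals <- numeric(60)
  for (s in seq_len(60)) {
    stim <- run_session(scene_config(n_items = 5), n_trials = 12,
                        seed = 400 + s, store_tracks = FALSE)
    obs <- observer_config(p_express = 0, p_regular = 0, p_press = 0,
                           blink_rate = 0)
    resp <- simulate_responses(stim, obs, seed = 500 + s)
    res <- pre_post_saccade_counts(resp$gaze, stim$displacements)
    pvals[s] <- if (identical(res$t_test$flag, "zero_variance")) 1
      else res$t_test$p
  }
  expect_gte(mean(pvals > 0.05), 0.9)
})
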