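# shared in-code fixtures; everything is generated at test time

DT_MS <- 1000 / 60

# gaze data frame from coordinate vectors (uniform 60 Hz grid)
make_trace <- function(x, y = rep(0, length(x)), valid = rep(TRUE, length(x))) {
  data.frame(time_ms = (seq_along(x) - 1) * DT_MS, x = x, y = y,
             valid = valid)
}

# flat fixation trace with optional white Gaussian jitter
make_fixation_trace <- function(n, sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_trace(stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd))
}

# inject the observer's constant-acceleration 3-sample movement so that
# samples k, k+1, k+2 move from the current position at k-1 to (tx, ty)
inject_movement <- function(trace, k, tx, ty) {
  prof <- c(1 / 9, 4 / 9, 1)
  sx <- trace$x[k - 1]; sy <- trace$y[k - 1]
  trace$x[k:(k + 2)] <- sx + (tx - sx) * prof
  trace$y[k:(k + 2)] <- sy + (ty - sy) * prof
  # hold at the target afterwards so only one acceleration burst exists
  if (k + 3 <= nrow(trace)) {
    trace$x[(k + 3):nrow(trace)] <- tx
    trace$y[(k + 3):nrow(trace)] <- ty
  }
  trace
}

# single-trial displacement row in the format of run_session()$displacements
make_disp_row <- function(time_ms, pre = c(0, 5), post = pre + c(2, 0),
                          v = c(18, 0), trial_id = 1L) {
  data.frame(time_ms = time_ms, item_id = 1L,
             rel_orientation_deg = 0, amplitude_deg =
               sqrt(sum((post - pre)^2)),
             pre_x = pre[1], pre_y = pre[2], post_x = post[1],
             post_y = post[2], vx = v[1], vy = v[2], trial_id = trial_id)
}

# analytically discretized bivariate Gaussian as a density_grid
make_gaussian_grid <- function(center = c(0, 0), cov = diag(2) * 0.01,
                               grid_size = 101, lim = c(-0.5, 0.5)) {
  gx <- seq(lim[1], lim[2], length.out = grid_size)
  ci <- solve(cov)
  dx <- outer(gx - center[1], rep(1, grid_size))
  dy <- outer(rep(1, grid_size), gx - center[2])
  q <- ci[1, 1] * dx^2 + 2 * ci[1, 2] * dx * dy + ci[2, 2] * dy^2
  g <- exp(-q / 2)
  g <- g / sum(g)
  structure(list(grid = g, x = gx, y = gx, cell_size = gx[2] - gx[1],
                 bandwidth = c(NA, NA), n = grid_size^2),
            class = "density_grid")
}

# displacement table drawn directly on the design grid (no scene simulation);
# orientations balanced, amplitudes uniform on the 0.5..8 grid, motion
# directions uniform. Used where the kernel machinery is the unit under test.
make_displacement_table <- function(n, seed = 1, speed = 18) {
  set.seed(seed)
  orients <- sample(rep(c(0, 45, -45, 90, -90, 135, -135, 180),
                        ceiling(n / 8)))[seq_len(n)]
  amps <- sample(seq(0.5, 8, 0.5), n, replace = TRUE)
  heading <- stats::runif(n, 0, 2 * pi)
  theta <- heading + orients * pi / 180
  data.frame(time_ms = seq_len(n) * 3000, item_id = 1L,
             rel_orientation_deg = orients, amplitude_deg = amps,
             pre_x = 0, pre_y = 0,
             post_x = amps * cos(theta), post_y = amps * sin(theta),
             vx = speed * cos(heading), vy = speed * sin(heading),
             trial_id = seq_len(n))
}

# label the trials of a displacement table with a logistic-in-Mahalanobis
# ground truth and return a bin_trials()-shaped outcome frame where detected
# trials are "explicit_only"
label_outcomes <- function(disp, center, cov, steepness, seed = 1) {
  set.seed(seed)
  nd <- normalize_displacements(disp)
  p <- detection_probability(cbind(nd$x, nd$y), center, cov, steepness)
  det <- stats::runif(nrow(disp)) < p
  data.frame(trial_id = disp$trial_id,
             category = ifelse(det, "explicit_only", "undetected"),
             press_latency_ms = NA_real_)
}

# full synthetic end-to-end run: stimulus + observer + detector + binning
run_synthetic_pipeline <- function(n_trials, obs, seed) {
  stim <- run_session(scene_config(), n_trials = n_trials, seed = seed,
                      store_tracks = FALSE)
  resp <- simulate_responses(stim, obs, seed = seed + 1000L)
  det <- detect_session_saccades(resp$gaze, stim$displacements)
  outcomes <- bin_trials(stim$displacements, det$saccades, resp$presses)
  list(stim = stim, resp = resp, det = det, outcomes = outcomes)
}
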