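#' Synthetic observer configuration
#'
#' Parameters of the simulated observer used to exercise the detection,
#' binning and kernel-recovery stages without real data. The observer fixates
#' the display center (white Gaussian tracker noise of SD `fixation_sd`), and
#' for each displacement independently decides "detected" with probability
#' [detection_probability()] under a ground-truth kernel. A detected trial
#' then independently triggers an express saccade (probability `p_express`,
#' onset uniform in `express_latency_range`), a regular saccade (`p_regular`,
#' `regular_latency_range`), and a button press (`p_press`,
#' `press_latency_range`).
#'
#' The ground-truth kernel `kernel_true` lives in motion-normalized
#' displacement units (displacement vector rotated into the motion frame and
#' divided by speed, so the usable radius is at most 8/18 ~ 0.44).
#'
#' Defaults state a plausible observer: a kernel elongated along the motion
#' direction (semi-axes 0.2 and 0.1 normalized units, eccentricity
#' sqrt(3)/2) with a small forward shift of the center (0.05), a logistic
#' steepness of 5, and response probabilities that qualitatively reproduce
#' the ordering explicit >> regular ~ express with a minority of mixed
#' response types.
#'
#' @param kernel_center,kernel_cov center (length 2) and 2x2 symmetric
#'   positive-definite covariance of the ground-truth kernel, normalized units.
#' @param steepness logistic slope on the Mahalanobis distance.
#' @param p_express,p_regular,p_press conditional response probabilities
#'   given detection.
#' @param express_latency_range,regular_latency_range,press_latency_range
#'   latency windows in ms (uniform draws).
#' @param fixation_sd SD of the fixation jitter, degrees.
#' @param min_saccade_deg smallest gaze-to-target distance that still evokes
#'   a saccade; closer targets are within the attended foveal region and
#'   yield no saccadic response (presses are unaffected).
#' @param blink_rate Poisson rate of blinks (events/s); blink durations are
#'   uniform in `blink_duration_ms`.
#' @param blink_duration_ms blink duration range, ms.
#' @param sample_rate gaze sample rate, Hz.
#' @return an object of class `observer_config`.
#' @export
observer_config <- function(kernel_center = c(0.05, 0),
                            kernel_cov = diag(c(0.2, 0.1)^2),
                            steepness = 5,
                            p_express = 0.2, p_regular = 0.2, p_press = 0.55,
                            express_latency_range = c(25, 150),
                            regular_latency_range = c(150, 250),
                            press_latency_range = c(300, 1200),
                            fixation_sd = 0.02,
                            min_saccade_deg = 1.5,
                            blink_rate = 0.1,
                            blink_duration_ms = c(100, 300),
                            sample_rate = 60) {
  stopifnot(length(kernel_center) == 2,
            is.matrix(kernel_cov), all(dim(kernel_cov) == 2))
  if (max(abs(kernel_cov - t(kernel_cov))) > 1e-12)
    stop("observer_config: kernel_cov must be symmetric", call. = FALSE)
  if (any(eigen(kernel_cov, symmetric = TRUE, only.values = TRUE)$values
          <= 0))
    stop("observer_config: kernel_cov must be positive definite",
         call. = FALSE)
  probs <- c(p_express, p_regular, p_press)
  if (any(probs < 0 | probs > 1))
    stop("observer_config: probabilities must lie in [0,1]", call. = FALSE)
  if (express_latency_range[2] > regular_latency_range[1])
    stop("observer_config: saccade latency ranges must be ordered and ",
         "non-overlapping", call. = FALSE)
  structure(list(kernel_center = kernel_center, kernel_cov = kernel_cov,
                 steepness = steepness, p_express = p_express,
                 p_regular = p_regular, p_press = p_press,
                 express_latency_range = express_latency_range,
                 regular_latency_range = regular_latency_range,
                 press_latency_range = press_latency_range,
                 fixation_sd = fixation_sd,
                 min_saccade_deg = min_saccade_deg,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 sample_rate = sample_rate),
            class = "observer_config")
}

#' Detection probability under a ground-truth kernel
#'
#' Logistic in the Mahalanobis distance M of the normalized displacement from
#' the kernel center under the kernel covariance:
#' `p = 1 / (1 + exp(-steepness * (M - 1)))`. Points on the 1-SD ellipse
#' (M = 1) are detected with probability 0.5; detection probability increases
#' strictly with M. With `steepness = 0` detection is independent of the
#' displacement (p = 0.5 everywhere), which is the null observer used for
#' calibration.
#'
#' @param xy numeric vector of length 2, or an n x 2 matrix of points in
#'   normalized displacement units.
#' @param center,cov kernel center and covariance (defaults: see `obs`).
#' @param steepness logistic slope.
#' @param obs optionally an [observer_config()] supplying center/cov/steepness.
#' @return detection probability (vector of length n).
#' @export
detection_probability <- function(xy, center = NULL, cov = NULL,
                                  steepness = NULL, obs = NULL) {
  if (!is.null(obs)) {
    if (is.null(center)) center <- obs$kernel_center
    if (is.null(cov)) cov <- obs$kernel_cov
    if (is.null(steepness)) steepness <- obs$steepness
  }
  if (is.null(center) || is.null(cov) || is.null(steepness))
    stop("detection_probability: supply center/cov/steepness or obs",
         call. = FALSE)
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  if (abs(det(cov)) < .Machine$double.xmin)
    stop("detection_probability: singular covariance", call. = FALSE)
  m <- sqrt(stats::mahalanobis(xy, center, cov))
  1 / (1 + exp(-steepness * (m - 1)))
}

# constant-acceleration 3-sample saccade waveform: fractions of the total
# movement completed at each in-flight sample
.saccade_profile <- c(1 / 9, 4 / 9, 1)

#' Simulate gaze and button responses for a stimulus session
#'
#' Generates a 60 Hz gaze trace (central fixation plus Gaussian jitter) and a
#' button-press log from a [stimulus_log] under an [observer_config()]. For
#' each displacement the trial is declared detected with probability
#' [detection_probability()] of its motion-normalized displacement; detected
#' trials independently receive an express saccade, a regular saccade and/or
#' a button press (see [observer_config()]). Saccades are ballistic 3-sample
#' constant-acceleration movements aimed at the displaced item's position at
#' saccade onset, hold the target for ~200 ms, then return to center. Blinks
#' are inserted as contiguous invalid runs at a Poisson rate. A response
#' whose latency draw would land beyond the next trial's onset is suppressed
#' and logged.
#'
#' @param stim a `stimulus_log` from [run_session()].
#' @param obs an [observer_config()].
#' @param seed integer seed (single RNG stream for all observer draws).
#' @return list with `gaze` (data frame `time_ms, x, y, valid`), `presses`
#'   (data frame `time_ms`), and `ground_truth` (per-trial data frame:
#'   `trial_id, p_detect, detected, express, regular, pressed,
#'   express_onset_ms, regular_onset_ms, press_ms, suppressed`).
#' @export
simulate_responses <- function(stim, obs = observer_config(), seed = 1) {
  disp <- stim$displacements
  if (nrow(disp) == 0) stop("simulate_responses: empty stimulus log",
                            call. = FALSE)
  with_seed(seed, {
    rate <- obs$sample_rate
    dt <- 1000 / rate
    n_samp <- as.integer(ceiling(stim$duration_ms / dt)) + 1L
    t_ms <- (seq_len(n_samp) - 1L) * dt

    gx <- stats::rnorm(n_samp, 0, obs$fixation_sd)
    gy <- stats::rnorm(n_samp, 0, obs$fixation_sd)

    nd <- normalize_displacements(disp)
    p <- detection_probability(cbind(nd$x, nd$y), obs = obs)
    detected <- stats::runif(nrow(disp)) < p

    next_onset <- c(disp$time_ms[-1], stim$duration_ms)

    gt <- data.frame(trial_id = disp$trial_id, p_detect = p,
                     detected = detected,
                     express = FALSE, regular = FALSE, pressed = FALSE,
                     express_onset_ms = NA_real_, regular_onset_ms = NA_real_,
                     press_ms = NA_real_, suppressed = FALSE)

    # planned saccades: collect, then render in time order
    sac_onset <- numeric(0)
    sac_trial <- integer(0)
    for (i in seq_len(nrow(disp))) {
      if (!detected[i]) next
      if (stats::runif(1) < obs$p_express) {
        on <- disp$time_ms[i] + stats::runif(1, obs$express_latency_range[1],
                                             obs$express_latency_range[2])
        if (on >= next_onset[i]) gt$suppressed[i] <- TRUE else {
          sac_onset <- c(sac_onset, on); sac_trial <- c(sac_trial, i)
          gt$express[i] <- TRUE; gt$express_onset_ms[i] <- on
        }
      }
      if (stats::runif(1) < obs$p_regular) {
        on <- disp$time_ms[i] + stats::runif(1, obs$regular_latency_range[1],
                                             obs$regular_latency_range[2])
        if (on >= next_onset[i]) gt$suppressed[i] <- TRUE else {
          sac_onset <- c(sac_onset, on); sac_trial <- c(sac_trial, i)
          gt$regular[i] <- TRUE; gt$regular_onset_ms[i] <- on
        }
      }
      if (stats::runif(1) < obs$p_press) {
        pm <- disp$time_ms[i] + stats::runif(1, obs$press_latency_range[1],
                                             obs$press_latency_range[2])
        if (pm >= next_onset[i]) gt$suppressed[i] <- TRUE else {
          gt$pressed[i] <- TRUE; gt$press_ms[i] <- pm
        }
      }
    }

    # render saccades into the trace, earliest first
    hold_samples <- as.integer(round(200 / dt))
    ord <- order(sac_onset)
    for (j in ord) {
      i <- sac_trial[j]
      k <- as.integer(round(sac_onset[j] / dt)) + 1L  # first moving sample
      if (k < 2L || k + 2L > n_samp) next
      t_on <- t_ms[k]
      # item position at saccade onset (linear post-displacement motion)
      tgt_x <- disp$post_x[i] + disp$vx[i] * (t_on - disp$time_ms[i]) / 1000
      tgt_y <- disp$post_y[i] + disp$vy[i] * (t_on - disp$time_ms[i]) / 1000
      sx <- gx[k - 1L]; sy <- gy[k - 1L]
      if (sqrt((tgt_x - sx)^2 + (tgt_y - sy)^2) < obs$min_saccade_deg) {
        # target inside the attended foveal region: no saccade executed
        which_col <- if (isTRUE(gt$express_onset_ms[i] == sac_onset[j]))
          "express" else "regular"
        gt[[which_col]][i] <- FALSE
        gt[[paste0(which_col, "_onset_ms")]][i] <- NA_real_
        next
      }
      gx[k:(k + 2L)] <- sx + (tgt_x - sx) * .saccade_profile
      gy[k:(k + 2L)] <- sy + (tgt_y - sy) * .saccade_profile
      hold_end <- min(k + 2L + hold_samples, n_samp)
      if (hold_end > k + 2L) {
        idx <- (k + 3L):hold_end
        gx[idx] <- tgt_x + stats::rnorm(length(idx), 0, obs$fixation_sd)
        gy[idx] <- tgt_y + stats::rnorm(length(idx), 0, obs$fixation_sd)
      }
      # 3-sample return to center, then back to the baseline jitter
      if (hold_end + 3L <= n_samp) {
        ret <- (hold_end + 1L):(hold_end + 3L)
        gx[ret] <- tgt_x + (gx[hold_end + 3L] - tgt_x) * .saccade_profile
        gy[ret] <- tgt_y + (gy[hold_end + 3L] - tgt_y) * .saccade_profile
      }
    }

    valid <- rep(TRUE, n_samp)
    if (obs$blink_rate > 0) {
      n_blinks <- stats::rpois(1, obs$blink_rate * stim$duration_ms / 1000)
      if (n_blinks > 0) {
        starts <- sort(stats::runif(n_blinks, 0, stim$duration_ms))
        durs <- stats::runif(n_blinks, obs$blink_duration_ms[1],
                             obs$blink_duration_ms[2])
        for (bjj in seq_len(n_blinks)) {
          lo <- as.integer(ceiling(starts[bjj] / dt)) + 1L
          hi <- as.integer(floor((starts[bjj] + durs[bjj]) / dt)) + 1L
          if (hi >= lo) valid[max(1L, lo):min(n_samp, hi)] <- FALSE
        }
      }
    }

    presses <- data.frame(time_ms = sort(gt$press_ms[gt$pressed]))
    gaze <- data.frame(time_ms = t_ms, x = gx, y = gy, valid = valid)
    list(gaze = gaze, presses = presses, ground_truth = gt)
  })
}

#' Write / read gaze and press logs
#'
#' Plain CSV round-trip for the gaze trace (`time_ms, x, y, valid`) and the
#' button-press log (`time_ms`).
#'
#' @param gaze,presses data frames as produced by [simulate_responses()].
#' @param path file path.
#' @return the path (writers) / a data frame (readers).
#' @export
write_gaze <- function(gaze, path) {
  utils::write.csv(gaze, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  g <- utils::read.csv(path)
  g$valid <- as.logical(g$valid)
  g
}

#' @rdname write_gaze
#' @export
write_presses <- function(presses, path) {
  utils::write.csv(presses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_presses <- function(path) utils::read.csv(path)
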