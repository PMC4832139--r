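#' Interpolate short invalid runs (blinks) in a gaze trace
#'
#' Invalid runs of at most `max_gap_ms` flanked by valid samples are filled
#' by linear interpolation and marked valid (`interpolated = TRUE`); longer
#' runs, and runs touching the trace edges, stay invalid. No samples are
#' added or removed.
#'
#' @param trace gaze data frame (`time_ms, x, y, valid`), uniformly sampled.
#' @param max_gap_ms longest gap that is still interpolated (default 200 ms).
#' @return the trace with filled samples and an added `interpolated` column.
#' @export
interpolate_blinks <- function(trace, max_gap_ms = 200) {
  if (!any(trace$valid))
    stop("interpolate_blinks: trace has no valid samples", call. = FALSE)
  n <- nrow(trace)
  trace$interpolated <- FALSE
  if (all(trace$valid)) return(trace)
  r <- rle(trace$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- if (n > 1) trace$time_ms[2] - trace$time_ms[1] else Inf
  for (j in which(!r$values)) {
    s <- starts[j]; e <- ends[j]
    if (s == 1L || e == n) next               # edge gap: cannot interpolate
    if ((e - s + 1L) * dt > max_gap_ms) next  # too long
    i0 <- s - 1L; i1 <- e + 1L
    w <- (trace$time_ms[s:e] - trace$time_ms[i0]) /
      (trace$time_ms[i1] - trace$time_ms[i0])
    trace$x[s:e] <- trace$x[i0] + w * (trace$x[i1] - trace$x[i0])
    trace$y[s:e] <- trace$y[i0] + w * (trace$y[i1] - trace$y[i0])
    trace$valid[s:e] <- TRUE
    trace$interpolated[s:e] <- TRUE
  }
  trace
}

#' Per-sample acceleration magnitude of a gaze trace
#'
#' Velocity is the forward first difference of position times the sample
#' rate; acceleration is the forward first difference of the velocity
#' *vector* times the sample rate, and its Euclidean magnitude is returned.
#' `acc[i]` therefore uses samples i, i+1, i+2 and is indexed at sample i;
#' the last two entries are `NA`. Invalid samples propagate as `NA`.
#'
#' @param trace gaze data frame (`time_ms, x, y, valid`).
#' @param sample_rate sampling rate in Hz; inferred from the time stamps if
#'   omitted.
#' @return numeric vector of length `nrow(trace)`, degrees/s^2.
#' @export
acceleration_series <- function(trace, sample_rate = NULL) {
  n <- nrow(trace)
  if (n < 3) stop("acceleration_series: need at least 3 samples",
                  call. = FALSE)
  if (is.null(sample_rate))
    sample_rate <- 1000 / (trace$time_ms[2] - trace$time_ms[1])
  x <- ifelse(trace$valid, trace$x, NA_real_)
  y <- ifelse(trace$valid, trace$y, NA_real_)
  vx <- diff(x) * sample_rate
  vy <- diff(y) * sample_rate
  ax <- diff(vx) * sample_rate
  ay <- diff(vy) * sample_rate
  c(sqrt(ax^2 + ay^2), NA_real_, NA_real_)
}

#' Adaptive acceleration threshold for one trial
#'
#' Mean plus one (population) standard deviation of the acceleration
#' magnitude over the 2 s window preceding the displacement, computed over
#' valid (non-`NA`) samples only. Requires at least half the window's nominal
#' samples to be valid.
#'
#' @param acc acceleration magnitude series from [acceleration_series()].
#' @param time_ms sample time stamps aligned with `acc`.
#' @param t_disp displacement time, ms.
#' @param window_ms baseline window length (default 2000 ms).
#' @return the threshold in degrees/s^2, or `NA` (with a warning suppressed;
#'   callers flag the trial un-analyzable) if too few valid samples.
#' @export
adaptive_threshold <- function(acc, time_ms, t_disp, window_ms = 2000) {
  idx <- which(time_ms >= t_disp - window_ms & time_ms < t_disp)
  if (length(idx) == 0)
    stop("adaptive_threshold: empty baseline window", call. = FALSE)
  v <- acc[idx]
  v <- v[!is.na(v)]
  dt <- if (length(time_ms) > 1) time_ms[2] - time_ms[1] else window_ms
  nominal <- window_ms / dt
  if (length(v) < nominal / 2) return(NA_real_)
  mean(v) + pop_sd(v)
}

#' Classify a saccade latency
#'
#' Express for latencies in \[25, 150) ms, regular for \[150, 250\] ms,
#' otherwise unclassified (anticipatory below 25 ms, late above 250 ms).
#'
#' @param latency_ms onset latency relative to the displacement, ms.
#' @return character vector: `"express"`, `"regular"` or `"unclassified"`.
#' @export
classify_saccade <- function(latency_ms) {
  ifelse(is.finite(latency_ms) & latency_ms >= 25 & latency_ms < 150,
         "express",
         ifelse(is.finite(latency_ms) & latency_ms >= 150 & latency_ms <= 250,
                "regular", "unclassified"))
}

# target position (moving item, post-displacement path) at time t_ms;
# for t_ms < displacement time this is the pre-displacement path.
.target_position <- function(disp_row, t_ms, pre = FALSE) {
  dtn <- (t_ms - disp_row$time_ms) / 1000
  if (pre) {
    c(disp_row$pre_x + disp_row$vx * dtn, disp_row$pre_y + disp_row$vy * dtn)
  } else {
    c(disp_row$post_x + disp_row$vx * dtn, disp_row$post_y + disp_row$vy * dtn)
  }
}

# core event scan used by detection and by the pre/post validity counts:
# within sample indices `idx`, find onsets where acc > threshold and the
# instantaneous movement direction is within `cone_deg` of the line from
# current gaze to the (moving) target. One onset per supra-threshold run:
# the first sample of the run whose direction qualifies.
.scan_window <- function(trace, acc, idx, threshold, disp_row, cone_deg,
                         sample_rate, pre = FALSE) {
  out <- list()
  if (length(idx) == 0 || is.na(threshold)) return(out)
  supra <- !is.na(acc[idx]) & acc[idx] > threshold
  r <- rle(supra)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  n <- length(trace$x)
  for (j in which(r$values)) {
    run <- idx[starts[j]:ends[j]]
    for (i in run) {
      if (i + 1L > n) break
      vx <- (trace$x[i + 1L] - trace$x[i]) * sample_rate
      vy <- (trace$y[i + 1L] - trace$y[i]) * sample_rate
      if (!is.finite(vx) || !is.finite(vy) || (vx == 0 && vy == 0)) next
      tgt <- .target_position(disp_row, trace$time_ms[i], pre = pre)
      lx <- tgt[1] - trace$x[i]
      ly <- tgt[2] - trace$y[i]
      dev <- angle_between_deg(vx, vy, lx, ly)
      if (dev <= cone_deg) {
        out[[length(out) + 1L]] <- list(
          onset_ms = trace$time_ms[i],
          deviation_deg = dev,
          direction_deg = rad2deg(atan2(vy, vx)),
          peak_acc = max(acc[run], na.rm = TRUE))
        break
      }
    }
  }
  out
}

#' Detect target-directed saccades for one displacement
#'
#' Scans the post-displacement search window for samples whose acceleration
#' magnitude exceeds the trial's adaptive threshold and whose instantaneous
#' movement direction lies within +/- 22.5 degrees of the straight line from
#' the current gaze position to the displaced item (the item's
#' post-displacement position at that sample, since the item keeps moving).
#' Each supra-threshold run contributes at most one saccade event, classified
#' by [classify_saccade()].
#'
#' @param trace (blink-interpolated) gaze data frame.
#' @param disp_row one-row displacement data frame (one trial).
#' @param acc optional precomputed [acceleration_series()].
#' @param threshold optional precomputed [adaptive_threshold()].
#' @param search_ms search window after the displacement, ms.
#' @param cone_deg half-angle of the direction cone, degrees.
#' @return data frame of saccade events (possibly empty): `trial_id,
#'   onset_ms, latency_ms, klass, direction_deg, deviation_deg, peak_acc`.
#' @export
detect_target_saccades <- function(trace, disp_row, acc = NULL,
                                   threshold = NULL,
                                   search_ms = c(0, 250), cone_deg = 22.5) {
  sample_rate <- 1000 / (trace$time_ms[2] - trace$time_ms[1])
  if (is.null(acc)) acc <- acceleration_series(trace, sample_rate)
  if (is.null(threshold))
    threshold <- adaptive_threshold(acc, trace$time_ms, disp_row$time_ms)
  t0 <- disp_row$time_ms + search_ms[1]
  t1 <- disp_row$time_ms + search_ms[2]
  idx <- which(trace$time_ms > t0 & trace$time_ms <= t1)
  hits <- .scan_window(trace, acc, idx, threshold, disp_row, cone_deg,
                       sample_rate)
  if (length(hits) == 0) {
    return(data.frame(trial_id = integer(0), onset_ms = numeric(0),
                      latency_ms = numeric(0), klass = character(0),
                      direction_deg = numeric(0), deviation_deg = numeric(0),
                      peak_acc = numeric(0)))
  }
  onset <- vapply(hits, `[[`, numeric(1), "onset_ms")
  latency <- onset - disp_row$time_ms
  data.frame(trial_id = disp_row$trial_id,
             onset_ms = onset,
             latency_ms = latency,
             klass = classify_saccade(latency),
             direction_deg = vapply(hits, `[[`, numeric(1), "direction_deg"),
             deviation_deg = vapply(hits, `[[`, numeric(1), "deviation_deg"),
             peak_acc = vapply(hits, `[[`, numeric(1), "peak_acc"))
}

#' Detect saccades for every trial of a session
#'
#' Runs blink interpolation, computes the acceleration series once, then
#' applies [adaptive_threshold()] and [detect_target_saccades()] per trial.
#'
#' @param gaze raw gaze data frame (`time_ms, x, y, valid`).
#' @param displacements displacement table from a [run_session()] log.
#' @param search_ms,cone_deg see [detect_target_saccades()].
#' @param max_gap_ms see [interpolate_blinks()].
#' @return list with `saccades` (row-bound event data frame) and
#'   `unanalyzable` (trial ids whose baseline window had too few valid
#'   samples).
#' @export
detect_session_saccades <- function(gaze, displacements,
                                    search_ms = c(0, 250), cone_deg = 22.5,
                                    max_gap_ms = 200) {
  trace <- interpolate_blinks(gaze, max_gap_ms)
  dt <- trace$time_ms[2] - trace$time_ms[1]
  sample_rate <- 1000 / dt
  acc <- acceleration_series(trace, sample_rate)
  n_samp <- nrow(trace)
  # lightweight column views: data-frame access inside the trial loop is slow
  tr <- list(time_ms = trace$time_ms, x = trace$x, y = trace$y)
  nt <- nrow(displacements)
  events <- vector("list", nt)
  bad <- integer(0)
  win_lo <- search_ms[1] / dt
  win_hi <- search_ms[2] / dt
  base_n <- 2000 / dt
  for (i in seq_len(nt)) {
    t_disp <- displacements$time_ms[i]
    m <- t_disp / dt  # event frame index (events snap to frames)
    # baseline window [t-2000, t): sample indices (time = (i-1)*dt)
    b_lo <- max(1L, as.integer(ceiling(m - base_n + 1 - 1e-7)))
    b_hi <- min(n_samp, as.integer(floor(m + 1 - 1e-7)) - 1L)
    v <- acc[b_lo:b_hi]
    v <- v[!is.na(v)]
    if (length(v) < base_n / 2) {
      bad <- c(bad, displacements$trial_id[i])
      next
    }
    thr <- mean(v) + pop_sd(v)
    # search window (t + lo, t + hi]
    s_lo <- max(1L, as.integer(floor(m + win_lo + 1 + 1e-7)) + 1L)
    s_hi <- min(n_samp, as.integer(floor(m + win_hi + 1 + 1e-7)))
    if (s_lo > s_hi) next
    row <- list(time_ms = t_disp,
                trial_id = displacements$trial_id[i],
                pre_x = displacements$pre_x[i],
                pre_y = displacements$pre_y[i],
                post_x = displacements$post_x[i],
                post_y = displacements$post_y[i],
                vx = displacements$vx[i], vy = displacements$vy[i])
    hits <- .scan_window(tr, acc, s_lo:s_hi, thr, row, cone_deg, sample_rate)
    if (length(hits) > 0) {
      onset <- vapply(hits, `[[`, numeric(1), "onset_ms")
      latency <- onset - t_disp
      events[[i]] <- data.frame(
        trial_id = row$trial_id, onset_ms = onset, latency_ms = latency,
        klass = classify_saccade(latency),
        direction_deg = vapply(hits, `[[`, numeric(1), "direction_deg"),
        deviation_deg = vapply(hits, `[[`, numeric(1), "deviation_deg"),
        peak_acc = vapply(hits, `[[`, numeric(1), "peak_acc"))
    }
  }
  events <- events[!vapply(events, is.null, logical(1))]
  saccades <- if (length(events)) do.call(rbind, events) else
    data.frame(trial_id = integer(0), onset_ms = numeric(0),
               latency_ms = numeric(0), klass = character(0),
               direction_deg = numeric(0), deviation_deg = numeric(0),
               peak_acc = numeric(0))
  list(saccades = saccades, unanalyzable = bad)
}

#' Pre/post displacement saccade counts (detector validity check)
#'
#' Counts target-directed supra-threshold movements in the 250 ms windows
#' before (`[t-250, t)`, relative to the item's pre-displacement path) and
#' after (`(t, t+250]`, relative to its post-displacement path) each
#' displacement, and returns the paired t statistic (post vs pre) across
#' trials.
#'
#' @param gaze raw gaze data frame.
#' @param displacements displacement table.
#' @param window_ms window length, ms.
#' @param cone_deg direction-cone half angle, degrees.
#' @return list with `pre`, `post` (per-trial counts), and `t_test`
#'   (result of [paired_t()]; `flag` is set when the count difference has
#'   zero variance, e.g. no movements at all).
#' @export
pre_post_saccade_counts <- function(gaze, displacements, window_ms = 250,
                                    cone_deg = 22.5) {
  if (nrow(displacements) < 2)
    stop("pre_post_saccade_counts: need at least 2 trials", call. = FALSE)
  trace <- interpolate_blinks(gaze)
  sample_rate <- 1000 / (trace$time_ms[2] - trace$time_ms[1])
  acc <- acceleration_series(trace, sample_rate)
  n <- nrow(displacements)
  pre <- post <- numeric(n)
  for (i in seq_len(n)) {
    row <- displacements[i, ]
    thr <- adaptive_threshold(acc, trace$time_ms, row$time_ms)
    if (is.na(thr)) { pre[i] <- NA; post[i] <- NA; next }
    idx_pre <- which(trace$time_ms >= row$time_ms - window_ms &
                       trace$time_ms < row$time_ms)
    idx_post <- which(trace$time_ms > row$time_ms &
                        trace$time_ms <= row$time_ms + window_ms)
    pre[i] <- length(.scan_window(trace, acc, idx_pre, thr, row, cone_deg,
                                  sample_rate, pre = TRUE))
    post[i] <- length(.scan_window(trace, acc, idx_post, thr, row, cone_deg,
                                   sample_rate))
  }
  ok <- !is.na(pre) & !is.na(post)
  list(pre = pre, post = post, t_test = paired_t(post[ok], pre[ok]))
}

#' Write saccade events to CSV
#' @param saccades event data frame from [detect_session_saccades()].
#' @param path file path.
#' @export
write_saccades <- function(saccades, path) {
  utils::write.csv(saccades, path, row.names = FALSE)
  invisible(path)
}
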