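#' Scene configuration for the moving-item display
#'
#' Builds the configuration of the stimulus display: a bounded rectangular
#' field in which identical circles move along linear trajectories at constant
#' speed and bounce off the boundaries. Defaults follow the experimental
#' setup: a 30 degree wide field of view at 4:3 aspect (22.5 degrees high),
#' 10 items of radius 1 degree moving at 18 degrees/s, with a +/- 0.001
#' degrees/s speed perturbation at every wall bounce.
#'
#' Items are treated as points for motion purposes, but the reflecting walls
#' sit at `+/-(width/2 - item_radius)` and `+/-(height/2 - item_radius)` so
#' that the circle never protrudes beyond the display. Distances to the
#' boundary (used by displacement eligibility) are measured to these motion
#' walls.
#'
#' @param width,height display extent in degrees of visual angle.
#' @param n_items number of moving circles.
#' @param item_radius circle radius in degrees.
#' @param speed nominal item speed in degrees/s.
#' @param bounce_jitter half-width of the uniform speed perturbation applied
#'   once per wall contact, in degrees/s.
#' @param frame_rate simulation frame rate in Hz (also the gaze sample rate).
#' @return an object of class `scene_config` (a named list).
#' @export
scene_config <- function(width = 30, height = 22.5, n_items = 10,
                         item_radius = 1, speed = 18, bounce_jitter = 0.001,
                         frame_rate = 60) {
  cfg <- list(width = width, height = height, n_items = n_items,
              item_radius = item_radius, speed = speed,
              bounce_jitter = bounce_jitter, frame_rate = frame_rate)
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$width) || cfg$width <= 0 ||
      !is.numeric(cfg$height) || cfg$height <= 0)
    stop("scene_config: width and height must be positive", call. = FALSE)
  if (!is.numeric(cfg$speed) || cfg$speed <= 0)
    stop("scene_config: speed must be positive", call. = FALSE)
  if (!is.numeric(cfg$item_radius) || cfg$item_radius <= 0)
    stop("scene_config: item_radius must be positive", call. = FALSE)
  if (cfg$n_items < 0)
    stop("scene_config: n_items must be >= 0", call. = FALSE)
  if (cfg$bounce_jitter < 0)
    stop("scene_config: bounce_jitter must be >= 0", call. = FALSE)
  if (cfg$frame_rate <= 0)
    stop("scene_config: frame_rate must be positive", call. = FALSE)
  # walls must leave room for motion
  if (cfg$width / 2 <= cfg$item_radius || cfg$height / 2 <= cfg$item_radius)
    stop("scene_config: item_radius too large for display", call. = FALSE)
  invisible(cfg)
}

# half-extent of the motion box (reflecting walls), per axis
motion_bounds <- function(cfg) {
  c(x = cfg$width / 2 - cfg$item_radius,
    y = cfg$height / 2 - cfg$item_radius)
}

#' Initialize item states
#'
#' Places `n_items` items uniformly at random inside the motion bounds with
#' uniformly random heading angles; every item starts at exactly
#' `config$speed`.
#'
#' @param config a [scene_config()].
#' @param seed optional integer seed; if supplied the RNG state is restored
#'   on exit.
#' @return a data frame with columns `item_id, x, y, vx, vy`.
#' @export
init_scene <- function(config, seed = NULL) {
  validate_scene_config(config)
  n <- config$n_items
  if (n == 0) {
    return(data.frame(item_id = integer(0), x = numeric(0), y = numeric(0),
                      vx = numeric(0), vy = numeric(0)))
  }
  with_seed(seed, {
    b <- motion_bounds(config)
    x <- stats::runif(n, -b["x"], b["x"])
    y <- stats::runif(n, -b["y"], b["y"])
    heading <- stats::runif(n, 0, 2 * pi)
    data.frame(item_id = seq_len(n),
               x = unname(x), y = unname(y),
               vx = config$speed * cos(heading),
               vy = config$speed * sin(heading))
  })
}

# Reflect a coordinate/velocity pair at +/-bound, tracking wall contacts.
# Works for arbitrary overshoot (multiple reflections).
.reflect_axis <- function(p, v, bound) {
  contacts <- 0L
  while (abs(p) > bound) {
    p <- if (p > bound) 2 * bound - p else -2 * bound - p
    v <- -v
    contacts <- contacts + 1L
  }
  list(p = p, v = v, contacts = contacts)
}

#' Advance item states by one time step
#'
#' Linear kinematics with reflecting boundaries. An item crossing a wall is
#' reflected (the velocity component normal to the wall changes sign) and its
#' speed is perturbed once per wall contact by a uniform draw in
#' `[-bounce_jitter, +bounce_jitter]` degrees/s. Items never exit the motion
#' bounds.
#'
#' @param items item-state data frame as returned by [init_scene()].
#' @param dt_ms time step in milliseconds.
#' @param config a [scene_config()].
#' @return updated item-state data frame.
#' @export
advance_items <- function(items, dt_ms, config) {
  if (dt_ms < 0) stop("advance_items: dt_ms must be >= 0", call. = FALSE)
  if (dt_ms == 0 || nrow(items) == 0) return(items)
  b <- motion_bounds(config)
  dt <- dt_ms / 1000
  x <- items$x + items$vx * dt
  y <- items$y + items$vy * dt
  vx <- items$vx
  vy <- items$vy
  oob <- which(abs(x) > b["x"] | abs(y) > b["y"])
  for (i in oob) {
    rx <- .reflect_axis(x[i], vx[i], b["x"])
    ry <- .reflect_axis(y[i], vy[i], b["y"])
    x[i] <- rx$p; vx[i] <- rx$v
    y[i] <- ry$p; vy[i] <- ry$v
    n_contacts <- rx$contacts + ry$contacts
    if (n_contacts > 0L && config$bounce_jitter > 0) {
      sp <- sqrt(vx[i]^2 + vy[i]^2)
      for (k in seq_len(n_contacts)) {
        sp_new <- sp + stats::runif(1, -config$bounce_jitter,
                                    config$bounce_jitter)
        vx[i] <- vx[i] * sp_new / sp
        vy[i] <- vy[i] * sp_new / sp
        sp <- sp_new
      }
    }
  }
  items$x <- x; items$y <- y; items$vx <- vx; items$vy <- vy
  items
}

# the fixed displacement design: motion-relative orientations (deg, CCW from
# the pre-displacement motion direction) and the amplitude grid (deg)
displacement_orientations <- function() c(0, 45, -45, 90, -90, 135, -135, 180)
displacement_amplitudes <- function() seq(0.5, 8, by = 0.5)

#' Sample one displacement event
#'
#' Draws an amplitude uniformly from the 0.5..8 (step 0.5) degree grid and a
#' motion-relative orientation uniformly from
#' \{0, +/-45, +/-90, +/-135, 180\} degrees (unless `orientation` is given,
#' e.g. from a counterbalanced deck), then picks an item uniformly among those
#' whose distance to every motion wall is at least twice the drawn amplitude.
#' If no item is eligible the amplitude (then item) is redrawn, up to
#' `max_attempts` times.
#'
#' @param items current item states.
#' @param config a [scene_config()].
#' @param time_ms session time stamp recorded in the event.
#' @param orientation optional fixed motion-relative orientation in degrees.
#' @param max_attempts bound on amplitude redraws before failing.
#' @return one-row data frame: `time_ms, item_id, rel_orientation_deg,
#'   amplitude_deg, pre_x, pre_y, post_x, post_y, vx, vy`.
#' @export
sample_displacement <- function(items, config, time_ms = 0,
                                orientation = NULL, max_attempts = 100) {
  if (nrow(items) == 0)
    stop("sample_displacement: no items in scene", call. = FALSE)
  st <- list(item_id = items$item_id, x = items$x, y = items$y,
             vx = items$vx, vy = items$vy)
  .sample_displacement_core(st, config, time_ms, orientation, max_attempts)
}

# vectorized core shared with run_session (st is a list of parallel vectors)
.sample_displacement_core <- function(st, config, time_ms, orientation,
                                      max_attempts) {
  b <- motion_bounds(config)
  amps <- displacement_amplitudes()
  wall_dist <- pmin(b[["x"]] - abs(st$x), b[["y"]] - abs(st$y))
  for (attempt in seq_len(max_attempts)) {
    a <- amps[sample.int(length(amps), 1)]
    eligible <- which(wall_dist >= 2 * a)
    if (length(eligible) > 0) {
      i <- eligible[sample.int(length(eligible), 1)]
      o <- if (is.null(orientation)) {
        os <- displacement_orientations()
        os[sample.int(length(os), 1)]
      } else orientation
      theta <- atan2(st$vy[i], st$vx[i]) + o * pi / 180
      return(data.frame(
        time_ms = time_ms,
        item_id = st$item_id[i],
        rel_orientation_deg = o,
        amplitude_deg = a,
        pre_x = st$x[i], pre_y = st$y[i],
        post_x = st$x[i] + a * cos(theta),
        post_y = st$y[i] + a * sin(theta),
        vx = st$vx[i], vy = st$vy[i]))
    }
  }
  stop("sample_displacement: no eligible item after ", max_attempts,
       " amplitude redraws", call. = FALSE)
}

#' Run a full stimulus session
#'
#' Advances the scene frame by frame at `config$frame_rate`, scheduling
#' `n_trials` displacement events whose successive onsets are separated by
#' fresh uniform draws in \[2000, 4000\] ms (snapped to the nearest frame).
#' Motion-relative orientations are counterbalanced: a balanced deck of the 8
#' orientations is shuffled once per session so each orientation occurs
#' `n_trials/8 +/- 1` times. Identical `(config, n_trials, seed)` reproduce
#' the log bit for bit.
#'
#' @param config a [scene_config()].
#' @param n_trials number of displacement events.
#' @param seed integer seed for the session's single RNG stream.
#' @param store_tracks keep the per-frame item-state table (needed to export
#'   `tracks.csv`; can be disabled to save memory in large simulations).
#' @return an object of class `stimulus_log`: list with `config`, `seed`,
#'   `displacements` (data frame, one row per trial in time order),
#'   `tracks` (data frame or NULL), `duration_ms`.
#' @export
run_session <- function(config = scene_config(), n_trials = 160, seed = 1,
                        store_tracks = TRUE) {
  validate_scene_config(config)
  if (n_trials < 0) stop("run_session: n_trials must be >= 0", call. = FALSE)
  with_seed(seed, {
    items <- init_scene(config)
    dt_ms <- 1000 / config$frame_rate

    gaps <- if (n_trials > 0) stats::runif(n_trials, 2000, 4000) else numeric(0)
    onset_ms <- cumsum(gaps)
    onset_frame <- as.integer(round(onset_ms / dt_ms))

    deck <- if (n_trials > 0) {
      os <- displacement_orientations()
      full <- rep(os, ceiling(n_trials / length(os)))
      sample(full)[seq_len(n_trials)]
    } else numeric(0)

    # tail of quiet time after the last event so late responses fit
    n_frames <- if (n_trials > 0) max(onset_frame) + as.integer(
      round(2000 / dt_ms)) else as.integer(round(2000 / dt_ms))

    keep_tracks <- store_tracks && config$n_items > 0
    ni <- config$n_items
    tx <- ty <- if (keep_tracks)
      matrix(NA_real_, nrow = ni, ncol = n_frames + 1L) else NULL
    if (keep_tracks) {
      tx[, 1L] <- items$x
      ty[, 1L] <- items$y
    }

    # Work on plain vectors; advance in multi-frame linear jumps between
    # wall contacts and displacement events (identical frame-grid semantics
    # to a per-frame loop, but the loop count scales with the number of
    # bounces/events instead of the number of frames).
    st <- list(item_id = items$item_id, x = items$x, y = items$y,
               vx = items$vx, vy = items$vy)
    b <- motion_bounds(config)
    dts <- dt_ms / 1000
    events <- vector("list", n_trials)
    trial <- 1L
    f <- 0L
    while (f < n_frames) {
      ne <- if (trial <= n_trials) onset_frame[trial] else n_frames
      # frames until the first wall crossing (crossing = |pos| > bound,
      # strict, matching the per-frame reflection trigger); a zero velocity
      # component yields Inf (division by zero, bound > 0)
      ttx <- (b[["x"]] - st$x * sign(st$vx)) / abs(st$vx)
      tty <- (b[["y"]] - st$y * sign(st$vy)) / abs(st$vy)
      j_wall <- floor(min(ttx, tty, Inf) / dts) + 1
      j <- min(j_wall - 1, ne - f, n_frames - f)
      if (j >= 1) {
        j <- as.integer(j)
        if (keep_tracks) {
          steps <- seq_len(j) * dts
          tx[, f + 1L + seq_len(j)] <- st$x + outer(st$vx, steps)
          ty[, f + 1L + seq_len(j)] <- st$y + outer(st$vy, steps)
        }
        st$x <- st$x + st$vx * (j * dts)
        st$y <- st$y + st$vy * (j * dts)
        f <- f + j
      } else {
        # single frame containing a wall contact
        st$x <- st$x + st$vx * dts
        st$y <- st$y + st$vy * dts
        oob <- which(abs(st$x) > b[["x"]] | abs(st$y) > b[["y"]])
        for (i in oob) {
          rx <- .reflect_axis(st$x[i], st$vx[i], b[["x"]])
          ry <- .reflect_axis(st$y[i], st$vy[i], b[["y"]])
          st$x[i] <- rx$p; st$vx[i] <- rx$v
          st$y[i] <- ry$p; st$vy[i] <- ry$v
          n_contacts <- rx$contacts + ry$contacts
          if (n_contacts > 0L && config$bounce_jitter > 0) {
            sp <- sqrt(st$vx[i]^2 + st$vy[i]^2)
            for (k in seq_len(n_contacts)) {
              sp_new <- sp + stats::runif(1, -config$bounce_jitter,
                                          config$bounce_jitter)
              st$vx[i] <- st$vx[i] * sp_new / sp
              st$vy[i] <- st$vy[i] * sp_new / sp
              sp <- sp_new
            }
          }
        }
        f <- f + 1L
        if (keep_tracks) {
          tx[, f + 1L] <- st$x
          ty[, f + 1L] <- st$y
        }
      }
      while (trial <= n_trials && onset_frame[trial] == f) {
        ev <- .sample_displacement_core(st, config, time_ms = f * dt_ms,
                                        orientation = deck[trial],
                                        max_attempts = 100)
        i <- match(ev$item_id, st$item_id)
        st$x[i] <- ev$post_x
        st$y[i] <- ev$post_y
        if (keep_tracks) {
          tx[i, f + 1L] <- ev$post_x
          ty[i, f + 1L] <- ev$post_y
        }
        events[[trial]] <- ev
        trial <- trial + 1L
      }
    }
    items <- data.frame(item_id = st$item_id, x = st$x, y = st$y,
                        vx = st$vx, vy = st$vy)

    disp <- if (n_trials > 0) do.call(rbind, events) else
      data.frame(time_ms = numeric(0), item_id = integer(0),
                 rel_orientation_deg = numeric(0), amplitude_deg = numeric(0),
                 pre_x = numeric(0), pre_y = numeric(0),
                 post_x = numeric(0), post_y = numeric(0),
                 vx = numeric(0), vy = numeric(0))
    disp$trial_id <- seq_len(nrow(disp))

    tracks <- NULL
    if (keep_tracks) {
      frames <- rep(0:n_frames, each = ni)
      tracks <- data.frame(frame = frames,
                           time_ms = frames * dt_ms,
                           item_id = rep(st$item_id, n_frames + 1L),
                           x = as.vector(tx), y = as.vector(ty))
    }
    structure(list(config = config, seed = seed, displacements = disp,
                   tracks = tracks, duration_ms = n_frames * dt_ms),
              class = "stimulus_log")
  })
}

#' @export
print.stimulus_log <- function(x, ...) {
  cat("<stimulus_log>", nrow(x$displacements), "displacement events,",
      sprintf("%.1f s,", x$duration_ms / 1000),
      x$config$n_items, "items @", x$config$speed, "deg/s\n")
  invisible(x)
}

#' Write / read a stimulus log
#'
#' `write_stimulus_log()` writes `displacements.csv`, optionally `tracks.csv`,
#' and a `session.json` sidecar holding the scene configuration and seed into
#' `dir`. `read_stimulus_log()` reconstructs the log (without tracks unless
#' present).
#'
#' @param log a `stimulus_log`.
#' @param dir output directory (created if missing).
#' @param tracks also write the per-frame track table if available.
#' @return `dir`, invisibly (writer); a `stimulus_log` (reader).
#' @export
write_stimulus_log <- function(log, dir, tracks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(log$displacements, file.path(dir, "displacements.csv"),
                   row.names = FALSE)
  if (tracks && !is.null(log$tracks))
    utils::write.csv(log$tracks, file.path(dir, "tracks.csv"),
                     row.names = FALSE)
  sidecar <- c(unclass(log$config), list(seed = log$seed,
                                         duration_ms = log$duration_ms))
  jsonlite::write_json(sidecar, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stimulus_log
#' @export
read_stimulus_log <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  cfg <- scene_config(width = side$width, height = side$height,
                      n_items = side$n_items, item_radius = side$item_radius,
                      speed = side$speed, bounce_jitter = side$bounce_jitter,
                      frame_rate = side$frame_rate)
  disp <- utils::read.csv(file.path(dir, "displacements.csv"))
  tr_path <- file.path(dir, "tracks.csv")
  tracks <- if (file.exists(tr_path)) utils::read.csv(tr_path) else NULL
  structure(list(config = cfg, seed = side$seed, displacements = disp,
                 tracks = tracks, duration_ms = side$duration_ms),
            class = "stimulus_log")
}
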