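# internal helpers shared across modules

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; with seed = NULL the current stream is used as-is.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  code
}

# population standard deviation (n divisor)
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# absolute angle (degrees, in [0, 180]) between two 2D vectors
angle_between_deg <- function(ax, ay, bx, by) {
  dot <- ax * bx + ay * by
  crs <- ax * by - ay * bx
  abs(atan2(crs, dot)) * 180 / pi
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi
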