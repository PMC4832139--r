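#' Normalize displacements to the motion frame
#'
#' Rotates each displacement vector into its item's pre-displacement motion
#' frame (positive x along the direction of travel) and divides by the item's
#' speed, so a displacement of the full 8 degree amplitude has norm
#' 8/18 ~ 0.444 normalized units at the nominal 18 degrees/s.
#'
#' @param displacements displacement table with `pre_x, pre_y, post_x,
#'   post_y, vx, vy` columns.
#' @return data frame `trial_id, x, y` (normalized units; `trial_id` kept if
#'   present).
#' @export
normalize_displacements <- function(displacements) {
  dx <- displacements$post_x - displacements$pre_x
  dy <- displacements$post_y - displacements$pre_y
  speed <- sqrt(displacements$vx^2 + displacements$vy^2)
  if (any(speed == 0))
    stop("normalize_displacements: zero pre-displacement velocity",
         call. = FALSE)
  ct <- displacements$vx / speed
  st <- displacements$vy / speed
  out <- data.frame(x = (ct * dx + st * dy) / speed,
                    y = (-st * dx + ct * dy) / speed)
  if (!is.null(displacements$trial_id))
    out <- cbind(trial_id = displacements$trial_id, out)
  out
}

#' 2D Gaussian kernel density estimate on a fixed grid
#'
#' Product-Gaussian KDE evaluated on a `grid_size` x `grid_size` grid over
#' `[-0.5, 0.5]^2` normalized units (matching the displacement range
#' 8/18 < 0.5), normalized to sum to 1. Bandwidths default to Silverman's
#' rule per axis for bivariate data, `h_j = sd_j * n^(-1/6)`, with a
#' one-cell floor for degenerate axes.
#'
#' @param points data frame or matrix with columns `x, y`.
#' @param grid_size grid resolution per axis (default 101).
#' @param bandwidth optional length-2 numeric overriding the per-axis
#'   bandwidths.
#' @param lim grid limits (applied to both axes).
#' @return object of class `density_grid`: list with `grid` (matrix, rows =
#'   x cells, columns = y cells), `x`, `y` (cell centers), `cell_size`,
#'   `bandwidth`, `n`.
#' @export
estimate_density <- function(points, grid_size = 101, bandwidth = NULL,
                             lim = c(-0.5, 0.5)) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1],
                                              y = points[, 2])
  n <- nrow(points)
  if (n == 0) stop("estimate_density: no points", call. = FALSE)
  gx <- seq(lim[1], lim[2], length.out = grid_size)
  cell <- gx[2] - gx[1]
  if (is.null(bandwidth)) {
    hx <- stats::sd(points$x) * n^(-1 / 6)
    hy <- stats::sd(points$y) * n^(-1 / 6)
    if (!is.finite(hx) || hx <= 0) hx <- cell
    if (!is.finite(hy) || hy <= 0) hy <- cell
    bandwidth <- c(hx, hy)
  }
  kx <- stats::dnorm(outer(gx, points$x, "-") / bandwidth[1])
  ky <- stats::dnorm(outer(gx, points$y, "-") / bandwidth[2])
  g <- kx %*% t(ky)
  g <- g / sum(g)
  structure(list(grid = g, x = gx, y = gx, cell_size = cell,
                 bandwidth = bandwidth, n = n),
            class = "density_grid")
}

#' Rectified non-detection density
#'
#' Pointwise positive part of (undetected density - detected density),
#' renormalized to sum to 1. This is the density whose covariance ellipse is
#' the psychophysical kernel: it concentrates where displacements are more
#' likely to be missed than detected.
#'
#' @param detected,undetected `density_grid` objects on the same grid.
#' @return a `density_grid`.
#' @export
nondetection_density <- function(detected, undetected) {
  if (!identical(dim(detected$grid), dim(undetected$grid)) ||
      max(abs(detected$x - undetected$x)) > 1e-12)
    stop("nondetection_density: grid geometries differ", call. = FALSE)
  d <- pmax(undetected$grid - detected$grid, 0)
  s <- sum(d)
  if (s <= 0)
    stop("nondetection_density: degenerate kernel (densities identical)",
         call. = FALSE)
  out <- undetected
  out$grid <- d / s
  out$n <- detected$n + undetected$n
  out
}

#' Ellipse properties of a fitted 2D Gaussian
#'
#' Derives the four kernel properties from a center and covariance: `area` of
#' the 1-SD covariance ellipse (`pi * sqrt(det(cov))`), `eccentricity`
#' (`sqrt(1 - (b/a)^2)` with `a >= b` the square roots of the eigenvalues),
#' `shift` (Euclidean norm of the center) and `orientation` (angle of the
#' major eigenvector against +x, degrees in (-90, 90]). Near-circular fits
#' (semi-axis ratio b/a > 0.95) are flagged `circular` and report
#' orientation 0, since the major-axis angle of a circle is meaningless.
#'
#' @param center numeric length-2 center.
#' @param covariance 2x2 symmetric positive semi-definite matrix.
#' @param circular_ratio axis ratio above which the fit is treated as
#'   circular.
#' @return list: `center, covariance, area, eccentricity, shift, orientation,
#'   semi_axes, circular, center_x` (`center_x` is the signed along-motion
#'   diagnostic projection).
#' @export
ellipse_properties <- function(center, covariance, circular_ratio = 0.95) {
  ev <- eigen(covariance, symmetric = TRUE)
  if (ev$values[2] < 0 && ev$values[2] > -1e-12) ev$values[2] <- 0
  if (any(ev$values < 0))
    stop("ellipse_properties: covariance not positive semi-definite",
         call. = FALSE)
  if (ev$values[2] <= 0)
    stop("ellipse_properties: degenerate kernel (covariance rank < 2)",
         call. = FALSE)
  a <- sqrt(ev$values[1])
  b <- sqrt(ev$values[2])
  circular <- (b / a) > circular_ratio
  orientation <- if (circular) 0 else {
    ang <- rad2deg(atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
    if (ang <= -90) ang <- ang + 180
    if (ang > 90) ang <- ang - 180
    ang
  }
  list(center = center, covariance = covariance,
       area = pi * a * b,
       eccentricity = sqrt(1 - (b / a)^2),
       shift = sqrt(sum(center^2)),
       orientation = orientation,
       semi_axes = c(a, b),
       circular = circular,
       center_x = center[1])
}

#' Fit a psychophysical kernel to a non-detection density
#'
#' Draws `n_samples` points from the density grid (cells with probability
#' proportional to their mass, uniform jitter within each cell), takes the
#' sample mean and covariance, and derives the kernel properties via
#' [ellipse_properties()]. Deterministic under a fixed seed.
#'
#' @param D a `density_grid` (normalized, non-degenerate).
#' @param n_samples number of sampled points (default 1000).
#' @param seed optional integer seed.
#' @return object of class `psy_kernel`: the [ellipse_properties()] list plus
#'   `n_samples`, `n_points` (trials behind the density).
#' @export
fit_kernel <- function(D, n_samples = 1000, seed = NULL) {
  stopifnot(inherits(D, "density_grid"))
  p <- as.vector(D$grid)
  if (sum(p) <= 0) stop("fit_kernel: degenerate density", call. = FALSE)
  with_seed(seed, {
    idx <- sample.int(length(p), n_samples, replace = TRUE, prob = p)
    gs <- length(D$x)
    ix <- ((idx - 1L) %% gs) + 1L      # row index = x cell
    iy <- ((idx - 1L) %/% gs) + 1L     # column index = y cell
    half <- D$cell_size / 2
    sx <- D$x[ix] + stats::runif(n_samples, -half, half)
    sy <- D$y[iy] + stats::runif(n_samples, -half, half)
    ctr <- c(mean(sx), mean(sy))
    cv <- stats::cov(cbind(sx, sy))
    dimnames(cv) <- NULL
    k <- ellipse_properties(ctr, cv)
    k$n_samples <- n_samples
    k$n_points <- D$n
    class(k) <- "psy_kernel"
    k
  })
}

#' @export
print.psy_kernel <- function(x, ...) {
  cat(sprintf(paste0("<psy_kernel> center (%.3f, %.3f)  area %.4f  ",
                     "ecc %.3f  shift %.3f  orient %.1f deg%s  (n=%d)\n"),
              x$center[1], x$center[2], x$area, x$eccentricity, x$shift,
              x$orientation, if (x$circular) " [circular]" else "",
              x$n_points))
  invisible(x)
}

#' Full reverse-correlation pipeline for one response category
#'
#' Composes normalization, detected/undetected density estimation, rectified
#' differencing and kernel fitting for the trials of one detection category
#' against the undetected trials. Categories with fewer than `min_trials`
#' detected or undetected trials are skipped (returns `NULL` with a message).
#'
#' @param outcomes trial outcome data frame from [bin_trials()].
#' @param displacements displacement table from the same session(s); must
#'   cover every `trial_id` in `outcomes`.
#' @param category detection category to estimate, e.g. `"explicit_only"`.
#' @param min_trials minimum detected and undetected trial counts.
#' @param grid_size,bandwidth passed to [estimate_density()].
#' @param n_samples,seed passed to [fit_kernel()].
#' @return a `psy_kernel` (with `category` field), or `NULL` if skipped.
#' @export
kernel_pipeline <- function(outcomes, displacements, category,
                            min_trials = 20, grid_size = 101,
                            bandwidth = NULL, n_samples = 1000, seed = NULL) {
  det_ids <- outcomes$trial_id[outcomes$category == category]
  und_ids <- outcomes$trial_id[outcomes$category == "undetected"]
  if (length(det_ids) < min_trials || length(und_ids) < min_trials) {
    message("kernel_pipeline: skipping '", category, "' (",
            length(det_ids), " detected / ", length(und_ids),
            " undetected trials, need ", min_trials, " each)")
    return(NULL)
  }
  nd <- normalize_displacements(displacements)
  det_pts <- nd[nd$trial_id %in% det_ids, c("x", "y")]
  und_pts <- nd[nd$trial_id %in% und_ids, c("x", "y")]
  f_det <- estimate_density(det_pts, grid_size, bandwidth)
  f_und <- estimate_density(und_pts, grid_size, bandwidth)
  D <- nondetection_density(f_det, f_und)
  k <- fit_kernel(D, n_samples = n_samples, seed = seed)
  k$category <- category
  k
}

#' Kernel table helpers
#'
#' `kernel_row()` flattens a `psy_kernel` into the one-row data frame used in
#' `kernels.csv` (`subject, category, center_x, center_y, cov_xx, cov_xy,
#' cov_yy, area, eccentricity, shift, orientation, n_points`);
#' `write_kernels()` writes a row-bound table.
#'
#' @param k a `psy_kernel`.
#' @param subject subject identifier.
#' @return one-row data frame.
#' @export
kernel_row <- function(k, subject = 1) {
  data.frame(subject = subject,
             category = if (is.null(k$category)) NA_character_ else k$category,
             center_x = k$center[1], center_y = k$center[2],
             cov_xx = k$covariance[1, 1], cov_xy = k$covariance[1, 2],
             cov_yy = k$covariance[2, 2],
             area = k$area, eccentricity = k$eccentricity,
             shift = k$shift, orientation = k$orientation,
             n_points = k$n_points)
}

#' @rdname kernel_row
#' @param kernels data frame of [kernel_row()]s.
#' @param path file path.
#' @export
write_kernels <- function(kernels, path) {
  utils::write.csv(kernels, path, row.names = FALSE)
  invisible(path)
}
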