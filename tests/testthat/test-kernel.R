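test_that("normalize_displacements rotates into the motion frame and
           divides by speed", {
  # motion +x, displacement (2, 0)
  d1 <- make_disp_row(0, pre = c(0, 0), post = c(2, 0), v = c(18, 0))
  n1 <- normalize_displacements(d1)
  expect_equal(c(n1$x, n1$y), c(2 / 18, 0))

  # motion +y, displacement along motion with amplitude 3
  d2 <- make_disp_row(0, pre = c(0, 0), post = c(0, 3), v = c(0, 18))
  n2 <- normalize_displacements(d2)
  expect_equal(c(n2$x, n2$y), c(3 / 18, 0))

  # motion +x, opposite displacement, amplitude 8
  d3 <- make_disp_row(0, pre = c(0, 0), post = c(-8, 0), v = c(18, 0))
  n3 <- normalize_displacements(d3)
  expect_equal(c(n3$x, n3$y), c(-8 / 18, 0))

  # perpendicular, +90 deg (CCW) from a -x motion
  d4 <- make_disp_row(0, pre = c(0, 0), post = c(0, -1), v = c(-18, 0))
  n4 <- normalize_displacements(d4)
  expect_equal(c(n4$x, n4$y), c(0, 1 / 18))

  d0 <- make_disp_row(0, v = c(0, 0))
  expect_error(normalize_displacements(d0), "zero")
})

test_that("estimate_density is a normalized, symmetric KDE with correct
           moments", {
  # single point at the origin: unimodal, peaked at the center cell, sum 1
  g1 <- estimate_density(data.frame(x = 0, y = 0), grid_size = 41)
  expect_equal(sum(g1$grid), 1)
  peak <- which(g1$grid == max(g1$grid), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(21, 21))

  # points symmetric about the x axis give a symmetric grid
  pts <- data.frame(x = c(0.1, 0.1, -0.2, -0.2, 0, 0),
                    y = c(0.15, -0.15, 0.3, -0.3, 0.05, -0.05))
  g2 <- estimate_density(pts, grid_size = 41)
  expect_lt(max(abs(g2$grid - g2$grid[, 41:1])), 1e-12)

  # moment oracle: grid mean/cov match sample moments + bandwidth inflation
  set.seed(51)
  n <- 4000
  xy <- cbind(rnorm(n, 0.05, 0.08), rnorm(n, 0, 0.06))
  g3 <- estimate_density(data.frame(x = xy[, 1], y = xy[, 2]),
                         grid_size = 101)
  gx <- outer(g3$x, rep(1, 101)); gy <- outer(rep(1, 101), g3$y)
  mx <- sum(gx * g3$grid); my <- sum(gy * g3$grid)
  vxx <- sum((gx - mx)^2 * g3$grid)
  vyy <- sum((gy - my)^2 * g3$grid)
  expect_lt(abs(mx - mean(xy[, 1])), 0.005)
  expect_lt(abs(my - mean(xy[, 2])), 0.005)
  expect_lt(abs(vxx - (var(xy[, 1]) + g3$bandwidth[1]^2)), 5e-4)
  expect_lt(abs(vyy - (var(xy[, 2]) + g3$bandwidth[2]^2)), 5e-4)

  expect_error(estimate_density(data.frame(x = numeric(0),
                                           y = numeric(0))), "no points")
})

test_that("nondetection_density is the rectified renormalized difference", {
  gA <- make_gaussian_grid(c(0, 0), diag(2) * 0.005)
  gB <- make_gaussian_grid(c(0.15, 0), diag(2) * 0.02)
  expect_error(nondetection_density(gA, gA), "degenerate")

  zero <- gA; zero$grid <- gA$grid * 0
  D <- nondetection_density(zero, gA)
  expect_equal(D$grid, gA$grid)

  # detected mass far out, undetected near the origin: D peaks near origin
  D2 <- nondetection_density(gB, gA)
  expect_equal(sum(D2$grid), 1)
  expect_true(all(D2$grid >= 0))
  peak <- which(D2$grid == max(D2$grid), arr.ind = TRUE)
  expect_lt(abs(D2$x[peak[1, 1]]), 0.03)
  expect_lt(abs(D2$y[peak[1, 2]]), 0.03)
})

test_that("ellipse_properties matches closed forms", {
  s2 <- 0.07^2
  p <- ellipse_properties(c(0, 0), diag(c(4 * s2, s2)))
  expect_equal(p$eccentricity, sqrt(3) / 2)
  expect_equal(p$area, pi * sqrt(det(diag(c(4 * s2, s2)))))
  expect_equal(p$orientation, 0)
  expect_equal(p$shift, 0)

  # rotated covariance: orientation follows the major axis
  th <- 35 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cv <- R %*% diag(c(4 * s2, s2)) %*% t(R)
  p2 <- ellipse_properties(c(0.1, -0.05), cv)
  expect_equal(p2$orientation, 35, tolerance = 1e-8)
  expect_equal(p2$shift, sqrt(0.1^2 + 0.05^2))
  expect_equal(p2$eccentricity, sqrt(3) / 2, tolerance = 1e-10)

  # circular flag suppresses the (meaningless) orientation
  p3 <- ellipse_properties(c(0, 0), diag(2) * s2)
  expect_true(p3$circular)
  expect_equal(p3$orientation, 0)

  expect_error(ellipse_properties(c(0, 0), diag(c(1, 0))), "degenerate")
})

test_that("fit_kernel recovers analytically specified Gaussians", {
  # isotropic at origin: ~zero eccentricity and shift (large n_samples to
  # tame the sample-covariance eigenvalue gap, which inflates ecc near 0)
  D0 <- make_gaussian_grid(c(0, 0), diag(2) * 0.01)
  k0 <- fit_kernel(D0, n_samples = 50000, seed = 61)
  expect_lt(k0$eccentricity, 0.2)
  expect_lt(k0$shift, 0.005)

  # 2:1 axis ratio: ecc sqrt(3)/2, orientation ~0, area ~ pi sqrt(det)
  s2 <- 0.07^2
  D1 <- make_gaussian_grid(c(0, 0), diag(c(4 * s2, s2)))
  k1 <- fit_kernel(D1, n_samples = 20000, seed = 62)
  expect_equal(k1$eccentricity, sqrt(3) / 2, tolerance = 0.05)
  expect_lt(abs(k1$orientation), 5)
  expect_equal(k1$area, pi * 2 * s2, tolerance = 0.05)

  # shifted center
  D2 <- make_gaussian_grid(c(0.2, 0), diag(2) * 0.004)
  k2 <- fit_kernel(D2, n_samples = 20000, seed = 63)
  expect_equal(k2$shift, 0.2, tolerance = 0.01)
  expect_equal(k2$center[1], 0.2, tolerance = 0.01)

  # determinism and basic invariants
  expect_equal(fit_kernel(D1, n_samples = 500, seed = 7),
               fit_kernel(D1, n_samples = 500, seed = 7))
  for (k in list(k0, k1, k2)) {
    expect_true(k$eccentricity >= 0 && k$eccentricity < 1)
    expect_gt(k$area, 0)
    expect_gte(k$shift, 0)
  }
})

test_that("the kernel is invariant under joint rotation of the raw data and
           mirror-symmetric across the motion axis", {
  disp <- make_displacement_table(800, seed = 64)
  out <- label_outcomes(disp, c(0.06, 0), diag(c(0.03, 0.012)), 5, seed = 65)

  # joint rotation of displacement vectors and motion directions leaves the
  # normalized coordinates (hence the kernel) exactly unchanged
  phi <- 73 * pi / 180
  rot <- function(x, y) cbind(cos(phi) * x - sin(phi) * y,
                              sin(phi) * x + cos(phi) * y)
  disp_r <- disp
  disp_r[, c("pre_x", "pre_y")] <- rot(disp$pre_x, disp$pre_y)
  disp_r[, c("post_x", "post_y")] <- rot(disp$post_x, disp$post_y)
  disp_r[, c("vx", "vy")] <- rot(disp$vx, disp$vy)
  expect_equal(normalize_displacements(disp_r), normalize_displacements(disp),
               tolerance = 1e-12)
  k <- kernel_pipeline(out, disp, "explicit_only", seed = 66)
  k_r <- kernel_pipeline(out, disp_r, "explicit_only", seed = 66)
  expect_equal(k_r$center, k$center, tolerance = 1e-9)
  expect_equal(k_r$eccentricity, k$eccentricity, tolerance = 1e-9)

  # mirroring across the motion axis: area/ecc/shift preserved, orientation
  # negated (up to resampling noise; the grid itself mirrors exactly)
  disp_m <- disp
  # reflect the motion-relative displacement: flip the perpendicular part
  nd <- normalize_displacements(disp)
  speed <- sqrt(disp$vx^2 + disp$vy^2)
  ct <- disp$vx / speed; st <- disp$vy / speed
  mx <- nd$x * speed; my <- -nd$y * speed
  disp_m$post_x <- disp$pre_x + ct * mx - st * my
  disp_m$post_y <- disp$pre_y + st * mx + ct * my
  k_m <- kernel_pipeline(out, disp_m, "explicit_only", n_samples = 20000,
                         seed = 67)
  k_hi <- kernel_pipeline(out, disp, "explicit_only", n_samples = 20000,
                          seed = 67)
  expect_equal(k_m$area, k_hi$area, tolerance = 0.05)
  expect_equal(k_m$eccentricity, k_hi$eccentricity, tolerance = 0.05)
  expect_lt(abs(k_m$shift - k_hi$shift), 0.01)
  expect_lt(abs(k_m$orientation - (-k_hi$orientation)), 3)
})

test_that("kernel_pipeline recovers a known ground-truth kernel and skips
           underpopulated categories", {
  true_c <- c(0.05, 0)
  true_cov <- diag(c(0.2, 0.1)^2)
  disp <- make_displacement_table(2000, seed = 71)
  out <- label_outcomes(disp, true_c, true_cov, 5, seed = 72)
  k <- kernel_pipeline(out, disp, "explicit_only", seed = 73)
  expect_lt(sqrt(sum((k$center - true_c)^2)), 0.05)
  expect_lt(abs(k$eccentricity - sqrt(3) / 2), 0.12)
  expect_equal(k$category, "explicit_only")
  expect_equal(k$n_points, sum(out$category %in% c("explicit_only",
                                                   "undetected")))

  # no detected trials in a category: skip with a message
  expect_message(
    k0 <- kernel_pipeline(out, disp, "express_only", seed = 74),
    "skipping")
  expect_null(k0)
})
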