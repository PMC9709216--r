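test_that("semi-foci distance follows the Pythagorean identity", {
  expect_equal(semi_foci(5, 3), 4)
  expect_equal(semi_foci(400, 250), sqrt(400^2 - 250^2)) # 312.41 um
  expect_equal(semi_foci(7, 7), 0)
  expect_error(semi_foci(3, 5), "Rb")
  expect_error(semi_foci(5, 0), "positive")
})

test_that("prolate coordinates invert and the local basis is orthonormal and right-handed", {
  geom <- prolate_geometry(centre = c(10, -5, 30), long_axis = c(0, 0, 1),
                           Ra = 100, Rb = 60)
  expect_equal(geom$f, 80)
  # equatorial point on +x: r = +x, c = +y, l = +z
  p_eq <- matrix(c(10 + 60, -5, 30), nrow = 1)
  b <- local_basis(p_eq, geom)
  expect_equal(drop(b$r_hat), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(drop(b$c_hat), c(0, 1, 0), tolerance = 1e-12)
  expect_equal(drop(b$l_hat), c(0, 0, 1), tolerance = 1e-12)
  # random points: orthonormality, handedness, coordinate round-trip
  set.seed(3)
  pc <- prolate_to_cartesian(runif(50, 0.3, 1.2), runif(50, 0.2, 2.6),
                             runif(50, -pi, pi), geom)
  bb <- local_basis(pc, geom)
  dot <- function(a, b) rowSums(a * b)
  expect_lt(max(abs(dot(bb$r_hat, bb$c_hat)) + abs(dot(bb$r_hat, bb$l_hat)) +
                  abs(dot(bb$c_hat, bb$l_hat))), 1e-9)
  cxl <- cbind(
    bb$c_hat[, 2] * bb$l_hat[, 3] - bb$c_hat[, 3] * bb$l_hat[, 2],
    bb$c_hat[, 3] * bb$l_hat[, 1] - bb$c_hat[, 1] * bb$l_hat[, 3],
    bb$c_hat[, 1] * bb$l_hat[, 2] - bb$c_hat[, 2] * bb$l_hat[, 1]
  )
  expect_lt(max(abs(cxl - bb$r_hat)), 1e-9)
  pcs <- prolate_coords(pc, geom)
  back <- prolate_to_cartesian(pcs$lambda_p, pcs$mu, pcs$theta, geom)
  expect_lt(max(abs(back - pc)), 1e-6)
  # reflection through the long axis flips the circumferential direction
  p <- matrix(c(10 + 45, -5 + 20, 60), nrow = 1)
  p_ref <- matrix(c(10 - 45, -5 - 20, 60), nrow = 1)
  b1 <- local_basis(p, geom)
  b2 <- local_basis(p_ref, geom)
  expect_equal(drop(b2$c_hat), -drop(b1$c_hat), tolerance = 1e-9)
  # on-axis points have no defined theta
  expect_error(local_basis(matrix(c(10, -5, 70), nrow = 1), geom), "axis")
})

test_that("prolate_geometry rejects non-prolate shapes", {
  expect_error(prolate_geometry(c(0, 0, 0), c(0, 0, 1), 50, 50), "Ra")
})

test_that("LV ellipsoid fit recovers phantom geometry and rejects degenerate masks", {
  sp <- phantom_spec(shape = rep(120, 3), voxel_size_um = 8, Ra_um = 400,
                     Rb_um = 250, rod_density = 1e-5, noise_sd = 0.02,
                     seed = 5)
  ph <- make_shell_phantom(sp, label_sectors = FALSE)
  geo <- fit_lv_ellipsoid(ph$mask, 8)
  expect_lt(abs(geo$Ra - 400) / 400, 0.05)
  expect_lt(abs(geo$Rb - 250) / 250, 0.05)
  expect_lt(abs(geo$f - semi_foci(400, 250)) / semi_foci(400, 250), 0.10)
  expect_gt(abs(geo$long_axis[3]), 0.999) # axis recovered
  # tiny mask rejected
  m10 <- array(0L, c(20, 20, 20)); m10[5:6, 5:6, 5:8] <- 1L
  expect_error(fit_lv_ellipsoid(m10, 8), "1000")
  # spherical shell: no prolate frame
  d <- c(40, 40, 40)
  ctr <- (40 - 1) / 2
  g <- expand.grid(x = 0:39, y = 0:39, z = 0:39)
  r <- sqrt((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2)
  sph <- array(as.integer(r >= 12 & r <= 16), d)
  expect_error(fit_lv_ellipsoid(sph, 8, refine = FALSE),
               "spherical|prolate|degenerate")
})

test_that("isotropic resampling is the identity on isotropic input and rescales z correctly", {
  v <- image_volume(array(rnorm(6 * 6 * 6), c(6, 6, 6)), 2)
  expect_identical(resample_isotropic(v), v)
  d <- c(20, 20, 100)
  vol <- image_volume(array(rnorm(prod(d)), d), c(2, 2, 3))
  iso <- resample_isotropic(vol)
  expect_true(is_isotropic(iso))
  expect_equal(iso$voxel_size_um, rep(2, 3))
  expect_equal(dim(iso$values)[3], 150) # 100 planes at 3 um -> 150 at 2 um
  # trilinear interpolation keeps linear fields exact
  g <- expand.grid(x = 0:19, y = 0:19, z = 0:99)
  lin <- image_volume(array(2 * g$x + g$y - 0.5 * g$z, d), c(2, 2, 3))
  lin_iso <- resample_isotropic(lin)
  gi <- expand.grid(x = 0:19, y = 0:19, z = seq_len(dim(lin_iso$values)[3]) - 1)
  truth <- 2 * gi$x + gi$y - 0.5 * pmin(gi$z * 2 / 3, 99) # source z clamped
  expect_lt(max(abs(lin_iso$values - truth)), 1e-6)
})

test_that("label resampling is nearest-neighbour and preserves the label set", {
  lab <- array(sample(0:3, 20 * 20 * 30, replace = TRUE), c(20, 20, 30))
  out <- resample_labels(lab, c(2, 2, 3), 2)
  expect_true(all(out %in% 0:3))
  expect_equal(dim(out)[3], 45)
})
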