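test_that("phantom_spec validates its fields with named messages", {
  expect_error(phantom_spec(shape = c(0, 10, 10)), "shape")
  expect_error(phantom_spec(voxel_size_um = -1), "voxel_size_um")
  expect_error(phantom_spec(Ra_um = 50, Rb_um = 50), "Ra_um")
  expect_error(phantom_spec(ha_endo_deg = 120), "ha_endo_deg")
  expect_error(phantom_spec(rod_density = 0), "rod_density")
  expect_error(phantom_spec(kappa = -1), "kappa")
  expect_error(phantom_spec(ha_endo_deg = 90, ia_deg = 30), "ia_deg")
})

test_that("slab truth axes realise the prescribed angles in the trivial frame", {
  sp0 <- phantom_spec(shape = c(16, 16, 14), geometry_kind = "slab",
                      ha_endo_deg = 0, ia_deg = 0, rod_density = 1e-4)
  ph0 <- make_slab_phantom(sp0)
  idx <- ph0$truth$mask_idx
  n <- prod(dim(ph0$mask))
  ax <- cbind(ph0$truth$axis[idx], ph0$truth$axis[idx + n],
              ph0$truth$axis[idx + 2 * n])
  expect_true(all(abs(abs(ax[, 1]) - 1) < 1e-12)) # axis = +/- x_hat
  sp90 <- phantom_spec(shape = c(16, 16, 14), geometry_kind = "slab",
                       ha_endo_deg = 90, ia_deg = 0, rod_density = 1e-4)
  ph90 <- make_slab_phantom(sp90)
  ax90 <- cbind(ph90$truth$axis[idx], ph90$truth$axis[idx + n],
                ph90$truth$axis[idx + 2 * n])
  expect_true(all(abs(abs(ax90[, 2]) - 1) < 1e-12)) # axis = +/- y_hat
})

test_that("identical spec and seed give identical phantoms; new seed differs", {
  sp <- phantom_spec(shape = c(24, 24, 20), geometry_kind = "slab", seed = 7)
  a <- make_slab_phantom(sp)
  b <- make_slab_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth$axis, b$truth$axis)
  sp8 <- phantom_spec(shape = c(24, 24, 20), geometry_kind = "slab", seed = 8)
  c8 <- make_slab_phantom(sp8)
  expect_false(identical(a$volume$values, c8$volume$values))
})

test_that("shell truth follows the linear transmural HA law", {
  ph <- shell_small()
  mid <- which(abs(ph$truth$depth - 0.5) < 0.01)
  expect_gt(length(mid), 10)
  expect_lt(max(abs(ph$truth$ha[mid])), 0.1 + 60 * 0.02 + 1e-9)
  # endo/epi endpoints approached
  endo <- which(ph$truth$depth < 0.02)
  expect_gt(min(ph$truth$ha[endo]), 55)
})

test_that("degenerate or unresolvable shells are rejected", {
  expect_error(phantom_spec(Ra_um = 60, Rb_um = 60), "degenerate")
  thin <- phantom_spec(shape = rep(64, 3), Ra_um = 100, Rb_um = 60,
                       wall_lambda_range = c(0.99, 1.01))
  expect_error(make_shell_phantom(thin), "unresolvable")
  slab_spec <- phantom_spec(geometry_kind = "slab")
  expect_error(make_shell_phantom(slab_spec), "geometry_kind")
})

test_that("truth HA/IA are self-consistent with the axes and local frame", {
  ph <- shell_small()
  idx <- ph$truth$mask_idx
  n <- prod(dim(ph$mask))
  ax <- cbind(ph$truth$axis[idx], ph$truth$axis[idx + n],
              ph$truth$axis[idx + 2 * n])
  ang <- myoarch:::axes_to_angles(ax, ph$truth$basis)
  expect_lt(max(abs(ang$ha - ph$truth$ha[idx])), 0.1)
  expect_lt(max(abs(ang$ia - ph$truth$ia[idx])), 0.1)
  # axes unit-norm inside the mask
  expect_lt(max(abs(rowSums(ax^2) - 1)), 1e-9)
})

test_that("perturb_axes: identity at kappa=Inf, isotropy at kappa=0, monotone dispersion", {
  ph <- slab_small()
  expect_identical(perturb_axes(ph$truth, Inf)$axis, ph$truth$axis)
  iso <- perturb_axes(ph$truth, 0, seed = 9)
  v <- myoarch:::truth_axes_matrix(iso)
  M <- crossprod(v) / nrow(v) # mean dyadic tensor ~ I/3
  expect_true(all(abs(diag(M) - 1 / 3) < 0.02))
  dev <- function(kappa) {
    pt <- perturb_axes(ph$truth, kappa, seed = 11)
    mean(axis_angle_deg(pt$axis, ph$truth$axis, ph$truth$mask_idx,
                        prod(dim(ph$mask))))
  }
  d20 <- dev(20); d5 <- dev(5); d1 <- dev(1)
  expect_lt(d20, d5)
  expect_lt(d5, d1)
})

test_that("rod texture is longer-range along the fiber axis than across it", {
  ph <- slab_small() # axis close to +x (HA 30 tilts toward +y)
  v <- ph$volume$values
  ac <- function(lag_dim) {
    d <- dim(v)
    a <- v[10:(d[1] - 10), 10:(d[2] - 10), 10:(d[3] - 10)]
    sh <- switch(lag_dim,
      v[(10:(d[1] - 10)) + 4, 10:(d[2] - 10), 10:(d[3] - 10)],
      v[10:(d[1] - 10), (10:(d[2] - 10)) + 4, 10:(d[3] - 10)],
      v[10:(d[1] - 10), 10:(d[2] - 10), (10:(d[3] - 10)) + 4])
    cor(as.vector(a), as.vector(sh))
  }
  expect_gt(ac(1), ac(3)) # along-axis correlation beats across-axis (radial z)
})
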