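make_vol <- function(f, d = c(12, 12, 12), vs = 2) {
  g <- expand.grid(x = seq_len(d[1]) - 1, y = seq_len(d[2]) - 1,
                   z = seq_len(d[3]) - 1)
  image_volume(array(f(g$x, g$y, g$z), dim = d), vs)
}

test_that("central differences are exact on linear fields and zero on constants", {
  ramp <- make_vol(function(x, y, z) x)
  g <- compute_gradient(ramp)
  inner <- g$interior
  expect_true(all(abs(g$gx[inner] - 1) < 1e-12))
  expect_true(all(abs(g$gy[inner]) < 1e-12))
  expect_true(all(abs(g$gz[inner]) < 1e-12))
  # one-sided at the border still recovers the exact slope of a linear field
  expect_true(all(abs(g$gx - 1) < 1e-12))
  flat <- make_vol(function(x, y, z) 5)
  gf <- compute_gradient(flat)
  expect_true(all(gf$gx == 0 & gf$gy == 0 & gf$gz == 0))
})

test_that("central differences match the analytic sine derivative to O(h^2)", {
  k <- 2 * pi / 16
  vol <- make_vol(function(x, y, z) sin(k * x), d = c(32, 8, 8))
  g <- compute_gradient(vol)
  xs <- matrix(rep(seq_len(32) - 1, times = 64), nrow = 32)
  truth <- array(k * cos(k * (seq_len(32) - 1)), dim = c(32, 8, 8))
  err <- abs(g$gx - truth)[2:31, , ]
  expect_lt(max(err), k - sin(k) + 1e-9) # discretisation bound sin(k)=k-k^3/6..
})

test_that("gradient demands isotropic voxels", {
  v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), c(2, 2, 3))
  expect_error(compute_gradient(v), "isotropic")
})

test_that("structure tensor matches a direct windowed-sum oracle", {
  set.seed(42)
  d <- c(9, 8, 7)
  gx <- array(rnorm(prod(d)), d)
  gy <- array(rnorm(prod(d)), d)
  gz <- array(rnorm(prod(d)), d)
  mask <- array(runif(prod(d)) > 0.3, d)
  grad <- structure(list(gx = gx, gy = gy, gz = gz,
                         interior = array(TRUE, d),
                         voxel_size_um = c(1, 1, 1)),
                    class = "gradient_field")
  tf <- compute_structure_tensor(grad, 3, mask)
  # brute-force oracle at a few interior voxels
  for (v in list(c(3, 3, 3), c(5, 4, 3), c(7, 6, 5))) {
    xs <- (v[1] - 1):(v[1] + 1); ys <- (v[2] - 1):(v[2] + 1)
    zs <- (v[3] - 1):(v[3] + 1)
    sel <- mask[xs, ys, zs]
    J <- matrix(0, 3, 3)
    for (i in seq_along(xs)) for (j in seq_along(ys)) for (k in seq_along(zs)) {
      if (!sel[i, j, k]) next
      gv <- c(gx[xs[i], ys[j], zs[k]], gy[xs[i], ys[j], zs[k]],
              gz[xs[i], ys[j], zs[k]])
      J <- J + gv %*% t(gv)
    }
    expect_equal(tf$xx[v[1], v[2], v[3]], J[1, 1], tolerance = 1e-12)
    expect_equal(tf$xy[v[1], v[2], v[3]], J[1, 2], tolerance = 1e-12)
    expect_equal(tf$yz[v[1], v[2], v[3]], J[2, 3], tolerance = 1e-12)
    expect_equal(tf$zz[v[1], v[2], v[3]], J[3, 3], tolerance = 1e-12)
  }
  # window precondition checks
  expect_error(compute_structure_tensor(grad, 4), "odd")
  expect_error(compute_structure_tensor(grad, 11), "extent")
})

test_that("uniform gradients give a rank-one tensor with the expected axis", {
  d <- c(8, 8, 8)
  grad <- structure(list(gx = array(1, d), gy = array(0, d),
                         gz = array(0, d), interior = array(TRUE, d),
                         voxel_size_um = c(1, 1, 1)),
                    class = "gradient_field")
  tf <- compute_structure_tensor(grad, 3)
  expect_true(all(tf$xx[3:6, 3:6, 3:6] == 27))
  expect_true(all(tf$yy == 0 & tf$zz == 0 & tf$xy == 0))
  o <- eigendecompose(tf, tau = 0) # degenerate l2 == l3: axis plane arbitrary
  expect_true(all(abs(o$v3[3:6, 3:6, 3:6, 1]) < 1e-9)) # v3 orthogonal to x
})

test_that("eigendecomposition sorts eigenvalues, pairs v3 with the smallest, and flags degeneracy", {
  d <- c(3, 3, 3)
  tf <- structure(list(
    xx = array(4, d), xy = array(0, d), xz = array(0, d),
    yy = array(1, d), yz = array(0, d), zz = array(0, d),
    n = array(27, d), window = 3, voxel_size_um = c(1, 1, 1)),
    class = "tensor_field")
  o <- eigendecompose(tf)
  expect_equal(o$l1[1], 4)
  expect_equal(o$l2[1], 1)
  expect_equal(o$l3[1], 0)
  expect_true(all(abs(abs(o$v3[, , , 3]) - 1) < 1e-12)) # v3 = +/- z_hat
  expect_true(all(o$valid))
  # isotropic tensor: no preferred axis -> invalid
  iso <- tf
  iso$yy <- array(4, d); iso$zz <- array(4, d)
  oi <- eigendecompose(iso)
  expect_false(any(oi$valid))
  # eigenvectors orthonormal when requested in full
  of <- eigendecompose(tf, full_vectors = TRUE)
  v1 <- of$v1[1, 1, 1, ]; v2 <- of$v2[1, 1, 1, ]; v3 <- of$v3[1, 1, 1, ]
  G <- rbind(v1, v2, v3) %*% cbind(v1, v2, v3)
  expect_equal(G, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fractional anisotropy matches its closed form and bounds", {
  expect_equal(fa_from_eigenvalues(1, 1, 1), 0)
  expect_equal(fa_from_eigenvalues(1, 0, 0), 1)
  expect_equal(fa_from_eigenvalues(2, 1, 1), 1 / sqrt(6), tolerance = 1e-12)
  expect_true(is.nan(fa_from_eigenvalues(0, 0, 0)))
  expect_error(fa_from_eigenvalues(1, -0.5, 0), "negative")
  set.seed(1)
  l <- matrix(abs(rnorm(300)), ncol = 3)
  fa <- fa_from_eigenvalues(l[, 1], l[, 2], l[, 3])
  expect_true(all(fa >= 0 & fa <= 1 + 1e-12))
})

test_that("orientation estimates are accurate and FA separates texture from noise", {
  ph <- slab_small()
  o <- slab_orientation()
  n <- prod(dim(ph$mask))
  idx <- which(o$valid & ph$mask == 1)
  ang <- axis_angle_deg(o$v3, ph$truth$axis, idx, n)
  expect_gte(mean(ang <= 5), 0.95)
  expect_lte(median(ang), 2.5)
  fa_rod <- fractional_anisotropy(o)
  set.seed(4)
  wn <- image_volume(array(rnorm(n), dim(ph$mask)), 2)
  g2 <- compute_gradient(wn, sigma_vox = 1)
  o2 <- eigendecompose(compute_structure_tensor(g2, 7, ph$mask), ph$mask)
  fa_wn <- fractional_anisotropy(o2)
  expect_gte(mean(fa_rod$fa[ph$mask == 1], na.rm = TRUE) -
               mean(fa_wn$fa[ph$mask == 1], na.rm = TRUE), 0.2)
  expect_true(all(fa_rod$fa[!is.na(fa_rod$fa)] <= 1 + 1e-12))
})
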