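# builds a one-voxel orientation field whose v3 is a prescribed combination
# of the local prolate basis vectors at a chosen point
angles_for_axis <- function(cc, ll, rr, method = "arcsin") {
  geom <- prolate_geometry(c(0, 0, 0), c(0, 0, 1), Ra = 100, Rb = 60)
  p <- matrix(c(60, 0, 0), nrow = 1) # equator: c = +y, l = +z, r = +x
  b <- local_basis(p, geom)
  v <- cc * b$c_hat + ll * b$l_hat + rr * b$r_hat
  d <- c(1, 1, 1)
  o <- structure(
    list(l1 = array(1, d), l2 = array(1, d), l3 = array(0, d),
         v3 = array(v, c(1, 1, 1, 3)), valid = array(TRUE, d),
         voxel_size_um = c(60, 60, 60), tau = 0.05), # voxel 0,0,0 -> 60,0,0?
    class = "orientation_field"
  )
  # place the single voxel at the equatorial point via voxel size trickery:
  # physical position of voxel (1,1,1) is (0,0,0); shift the geometry instead
  geom2 <- prolate_geometry(c(-60, 0, 0), c(0, 0, 1), Ra = 100, Rb = 60)
  am <- compute_angles(o, geom2, method = method)
  c(ha = am$ha[1, 1, 1], ia = am$ia[1, 1, 1])
}

test_that("helical and intrusion angles follow their defining identities", {
  a <- angles_for_axis(1, 0, 0)
  expect_equal(unname(a), c(0, 0), tolerance = 1e-9)
  a45 <- angles_for_axis(1 / sqrt(2), 1 / sqrt(2), 0)
  expect_equal(unname(a45["ha"]), 45, tolerance = 1e-9)
  expect_equal(unname(a45["ia"]), 0, tolerance = 1e-9)
  ai <- angles_for_axis(0.6, 0, 0.8)
  expect_equal(unname(ai["ha"]), 0, tolerance = 1e-9)
  expect_equal(unname(ai["ia"]), asin(0.8) * 180 / pi, tolerance = 1e-9) # 53.13
})

test_that("projected-angle variant matches atan2 in-plane reading", {
  a <- angles_for_axis(1 / sqrt(2), 1 / sqrt(2), 0, method = "projected")
  expect_equal(unname(a["ha"]), 45, tolerance = 1e-9)
  ai <- angles_for_axis(0.6, 0, 0.8, method = "projected")
  expect_equal(unname(ai["ia"]), atan2(0.8, 0.6) * 180 / pi, tolerance = 1e-9)
})

test_that("non-unit eigenvectors are rejected", {
  d <- c(1, 1, 1)
  o <- structure(
    list(l1 = array(1, d), l2 = array(1, d), l3 = array(0, d),
         v3 = array(c(2, 0, 0), c(1, 1, 1, 3)), valid = array(TRUE, d),
         voxel_size_um = c(60, 60, 60), tau = 0.05),
    class = "orientation_field"
  )
  geom <- prolate_geometry(c(-60, 0, 0), c(0, 0, 1), Ra = 100, Rb = 60)
  expect_error(compute_angles(o, geom), "unit")
})

test_that("angle maps are invariant under a global eigenvector sign flip", {
  ph <- shell_small()
  o <- truth_as_orientation(ph)
  geom <- ph$geometry
  a1 <- compute_angles(o, geom, ph$mask)
  o$v3 <- -o$v3
  a2 <- compute_angles(o, geom, ph$mask)
  expect_equal(a1$ha, a2$ha)
  expect_equal(a1$ia, a2$ia)
  # angle magnitudes are consistent with a unit axis
  sel <- !is.na(a1$ha)
  s2 <- sin(a1$ha[sel] * pi / 180)^2 + sin(a1$ia[sel] * pi / 180)^2
  expect_lt(max(s2), 1 + 1e-9)
  expect_true(all(abs(a1$ha[sel]) <= 90 & abs(a1$ia[sel]) <= 90))
})

test_that("angles recover the truth law on a clean shell phantom", {
  ph <- shell_small()
  g <- compute_gradient(ph$volume, sigma_vox = 1)
  o <- eigendecompose(compute_structure_tensor(g, 7, ph$mask), ph$mask)
  ang <- compute_angles(o, ph$geometry, ph$mask)
  err <- abs(ang$ha - ph$truth$ha)
  expect_lte(median(err[!is.na(err)]), 7.5)
  ia_err <- abs(ang$ia) # prescribed IA is 0
  expect_lte(median(ia_err[!is.na(ia_err)]), 7.5)
  # endo-positive to epi-negative progression
  endo_ha <- mean(ang$ha[!is.na(ang$ha) & ph$truth$depth < 0.2])
  epi_ha <- mean(ang$ha[!is.na(ang$ha) & ph$truth$depth > 0.8])
  expect_gt(endo_ha, 20)
  expect_lt(epi_ha, -20)
})
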