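uniform_orientation <- function(d, axis = c(1, 0, 0), vs = 2) {
  v3 <- array(0, c(d, 3))
  for (k in 1:3) v3[, , , k] <- axis[k]
  structure(
    list(l1 = array(1, d), l2 = array(1, d), l3 = array(0, d), v3 = v3,
         valid = array(TRUE, d), voxel_size_um = rep(vs, 3), tau = 0.05),
    class = "orientation_field"
  )
}

test_that("MDI is 1 for aligned axes and reports the physical window extent", {
  d <- c(15, 15, 15)
  o <- uniform_orientation(d)
  m <- compute_mdi(o, window = 11)
  expect_equal(m$mdi[8, 8, 8], 1, tolerance = 1e-9)
  expect_equal(m$window_extent_um, rep(22, 3)) # 11 voxels at 2 um
  o3 <- uniform_orientation(d, vs = 3)
  expect_equal(compute_mdi(o3, window = 11)$window_extent_um, rep(33, 3))
  expect_error(compute_mdi(o, window = 10), "odd")
  expect_error(compute_mdi(o, window = 1), ">= 3")
})

test_that("MDI of a half-x/half-y interleaved field is 1/4", {
  d <- c(15, 15, 15)
  o <- uniform_orientation(d)
  # checkerboard (x+y+z parity) alternation of +x / +y: every window is
  # half-and-half to within one voxel
  par <- (slice.index(array(0, d), 1) + slice.index(array(0, d), 2) +
            slice.index(array(0, d), 3)) %% 2 == 0
  o$v3[, , , 1][par] <- 0
  o$v3[, , , 2][par] <- 1
  m <- compute_mdi(o, window = 11)
  expect_lt(abs(m$mdi[8, 8, 8] - 0.25), 0.05)
})

test_that("MDI of isotropic axes is near 0 and decreases monotonically with kappa", {
  ph <- fixture("slab_mdi", function() {
    sp <- phantom_spec(shape = c(40, 40, 36), geometry_kind = "slab",
                      ha_endo_deg = 30, ia_deg = 10, seed = 11)
    make_slab_phantom(sp)
  })
  mean_mdi <- function(kappa) {
    tr <- perturb_axes(ph$truth, kappa, seed = 13)
    o <- truth_as_orientation(list(mask = ph$mask, truth = tr))
    mean(compute_mdi(o, ph$mask)$mdi, na.rm = TRUE)
  }
  m_inf <- mean_mdi(Inf); m20 <- mean_mdi(20); m5 <- mean_mdi(5); m0 <- mean_mdi(0)
  expect_equal(m_inf, 1, tolerance = 1e-9)
  expect_lte(m0, 0.1)
  expect_true(m_inf > m20 && m20 > m5 && m5 > m0)
})

test_that("MDI is undefined where under half the window is valid myocardium", {
  d <- c(15, 15, 15)
  o <- uniform_orientation(d)
  mask <- array(0L, d)
  mask[1:3, , ] <- 1L # thin plate: central windows mostly empty
  m <- compute_mdi(o, mask, window = 11)
  expect_true(all(is.na(m$mdi[mask == 1]))) # 3/11 of window valid < 50%
})

test_that("MDI agrees between dyadic and mean-dot variants on aligned fields", {
  d <- c(9, 9, 9)
  o <- uniform_orientation(d)
  m1 <- compute_mdi(o, window = 5)
  m2 <- compute_mdi(o, window = 5, method = "mean_dot")
  expect_equal(m1$mdi[5, 5, 5], 1, tolerance = 1e-9)
  expect_equal(m2$mdi[5, 5, 5], 1, tolerance = 1e-9)
})

test_that("angle classification applies the inclusive thresholds", {
  am <- list(ha = array(c(0, 15, 25, -25), c(4, 1, 1)),
             ia = array(c(10, 30, 50, -50), c(4, 1, 1)))
  cl <- classify_angles(am)
  expect_equal(cl$frac_circ, 0.5)
  expect_equal(cl$frac_long_pos, 0.25)
  expect_equal(cl$frac_long_neg, 0.25)
  expect_equal(cl$frac_ia_le15, 0.25)
  expect_equal(cl$frac_ia_15_45, 0.25)
  expect_equal(cl$frac_ia_gt45, 0.5)
  # |HA| = 20 is circumferential (boundary inclusive)
  am20 <- list(ha = array(c(20, -20, 20.001), c(3, 1, 1)),
               ia = array(0, c(3, 1, 1)))
  cl20 <- classify_angles(am20)
  expect_equal(cl20$frac_circ, 2 / 3)
  expect_equal(cl20$frac_long_pos, 1 / 3)
  expect_error(classify_angles(am, region_mask = array(0, c(4, 1, 1))),
               "empty")
  # triples sum to one
  expect_equal(cl$frac_circ + cl$frac_long_pos + cl$frac_long_neg, 1)
  expect_equal(cl$frac_ia_le15 + cl$frac_ia_15_45 + cl$frac_ia_gt45, 1)
})

test_that("region summaries are exact on constant regions and order-invariant", {
  d <- c(6, 6, 6)
  labels <- array(NA_integer_, d)
  labels[1:3, , ] <- 1L
  labels[4:6, , ] <- 2L
  fa <- array(0.5, d)
  mdi <- array(0.8, d)
  am <- list(ha = array(0, d), ia = array(0, d))
  s <- summarize_regions(labels, fa, mdi, am)
  expect_equal(nrow(s), 2)
  expect_equal(s$n_voxels, c(108, 108))
  expect_equal(s$mean_FA, c(0.5, 0.5))
  expect_equal(s$sd_FA, c(0, 0))
  expect_equal(s$frac_circ, c(1, 1))
  expect_equal(s$mean_HA, c(0, 0))
  # relabelling regions permutes rows but not values
  labels2 <- labels
  labels2[labels == 1L] <- 2L
  labels2[labels == 2L] <- 1L
  s2 <- summarize_regions(labels2, fa, mdi, am)
  expect_equal(s2$mean_FA, s$mean_FA)
  expect_error(summarize_regions(labels, fa = array(0.5, c(3, 3, 3))),
               "shapes")
})

test_that("region histograms conserve voxel counts", {
  d <- c(6, 6, 6)
  labels <- array(1L, d)
  set.seed(2)
  am <- list(ha = array(runif(216, -90, 90), d),
             ia = array(runif(216, -90, 90), d))
  h <- region_histograms(am, labels)
  tot <- dplyr::count(h, angle_type, wt = count)
  expect_equal(tot$n, c(216, 216))
  expect_equal(unique(h$bin_hi - h$bin_lo), 5)
})
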