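test_that("AHA segmentation partitions the LV wall with septal segments facing the RV", {
  ph <- shell_small()
  vs <- ph$spec$voxel_size_um
  seg <- aha_segmentation(ph$mask, ph$geometry, vs)
  lv <- ph$mask == 1 | ph$mask == 2
  expect_true(all(!is.na(seg[lv])))
  expect_true(all(is.na(seg[!lv])))
  expect_equal(sum(table(seg[lv])), sum(lv)) # labels + excluded partition LV
  expect_true(all(sort(unique(seg[lv & seg > 0])) %in% 1:16))
  # septal segments lie on the RV-facing side
  rv_idx <- which(ph$mask == 3)
  d <- dim(ph$mask)
  pts <- myoarch:::grid_coords_um(d, rep(vs, 3))
  anchor <- colMeans(pts[rv_idx, , drop = FALSE]) - ph$geometry$centre
  anchor <- anchor / sqrt(sum(anchor^2))
  for (s in c(2, 3, 8, 9, 14)) {
    sel <- which(!is.na(seg) & seg == s)
    expect_gt(length(sel), 0)
    ctr <- colMeans(pts[sel, , drop = FALSE]) - ph$geometry$centre
    expect_gt(sum(ctr * anchor), 0)
  }
  # apical cap exists and sits apical of every cavity voxel
  expect_gt(sum(seg == 0, na.rm = TRUE), 0)
  # without an RV label the anchor must be supplied
  lv_only <- ph$mask
  lv_only[lv_only == 3L] <- 0L
  expect_error(aha_segmentation(lv_only, ph$geometry, vs), "anchor")
  seg2 <- aha_segmentation(lv_only, ph$geometry, vs, anchor = anchor)
  expect_true(all(sort(unique(seg2[!is.na(seg2) & seg2 > 0])) %in% 1:16))
})

test_that("AHA summary covers 16 segments on the shell phantom", {
  ph <- shell_small()
  seg <- aha_segmentation(ph$mask, ph$geometry, 2)
  seg[!is.na(seg) & seg == 0] <- NA_integer_ # drop the excluded cap
  ang <- compute_angles(truth_as_orientation(ph), ph$geometry, ph$mask)
  fa <- array(0.5, dim(ph$mask))
  s <- summarize_regions(seg, fa = fa, angles = ang,
                         region_names = aha_segment_names())
  expect_equal(nrow(s), 16)
  expect_true(all(s$n_voxels > 0))
})

test_that("wall sectors and levels partition their slabs and rotate with the volume", {
  ph <- shell_small()
  vs <- ph$spec$voxel_size_um
  sect <- define_walls_and_levels(ph$mask, ph$geometry, vs)
  wall <- ph$mask != 0
  expect_true(all(!is.na(sect$sector[wall])))
  expect_true(all(is.na(sect$sector[!wall])))
  lv_wall <- ph$mask %in% c(1, 2)
  expect_true(all(sect$sector[lv_wall] %in% 1:4))
  expect_true(all(sect$sector[ph$mask == 3] %in% 5:7))
  lev <- sect$level[wall]
  expect_true(all(is.na(lev) | lev %in% 1:3))
  expect_true(all(1:3 %in% lev[!is.na(lev)]))
  # rotating the mask 90 degrees about the long axis rotates sector labels
  rot <- function(a) {
    d <- dim(a)
    aperm(a[, d[2]:1, , drop = FALSE], c(2, 1, 3))
  }
  mask_r <- rot(ph$mask)
  geom_r <- ph$geometry # centre symmetric, long axis unchanged by z-rotation
  sect_r <- define_walls_and_levels(mask_r, geom_r, vs)
  expect_equal(unname(table(sect_r$sector)), unname(table(sect$sector)))
  agree <- mean(rot(sect$sector) == sect_r$sector, na.rm = TRUE)
  expect_gt(agree, 0.98)
})
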