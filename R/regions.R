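# Per-voxel cylindrical coordinates about the LV long axis, with the
# circumferential angle measured from an anchor direction (mid-septum,
# i.e. toward the RV centroid), positive consistently with the prolate theta.
region_coords <- function(idx, dim, geometry, voxel_size_um, anchor) {
  pts <- grid_coords_um(dim, rep(voxel_size_um, length.out = 3))[idx, , drop = FALSE]
  p <- sweep(pts, 2, geometry$centre)
  u <- geometry$long_axis
  zeta <- drop(p %*% u)
  a1 <- anchor - sum(anchor * u) * u
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(u[2] * a1[3] - u[3] * a1[2],
          u[3] * a1[1] - u[1] * a1[3],
          u[1] * a1[2] - u[2] * a1[1])
  theta_rel <- rad2deg(atan2(drop(p %*% a2), drop(p %*% a1)))
  list(zeta = zeta, theta = theta_rel)
}

# Anchor direction toward the RV centroid; errors without RV voxels unless
# an explicit anchor is supplied.
resolve_anchor <- function(mask, geometry, voxel_size_um, anchor) {
  if (!is.null(anchor)) return(anchor / sqrt(sum(anchor^2)))
  rv <- which(mask == 3)
  if (length(rv) == 0) {
    stop("no RV voxels (label 3) to anchor the septum direction; ",
         "supply `anchor`", call. = FALSE)
  }
  pts <- grid_coords_um(dim(mask), rep(voxel_size_um, length.out = 3))[rv, , drop = FALSE]
  ctr <- colMeans(pts) - geometry$centre
  ctr / sqrt(sum(ctr^2))
}

#' AHA 16-segment labelling of the LV wall
#'
#' Partitions the LV compact wall (labels 1 and 2) into the standard AHA
#' segments: 6 basal, 6 mid-cavity and 4 apical segments by long-axis thirds
#' and circumferential sectors anchored at the mid-septum (the direction from
#' the LV centre toward the RV centroid). The apical cap — wall apical of the
#' tip of the LV cavity, where segment 17 would sit — is labelled 0 and
#' excluded from analysis. Every LV wall voxel receives exactly one of
#' 0..16; non-LV voxels are NA.
#'
#' @param mask label array (1 = LV free wall, 2 = septum, 3 = RV free wall).
#' @param geometry a [prolate_geometry()].
#' @param voxel_size_um voxel size (µm).
#' @param anchor optional unit direction toward the mid-septum, overriding
#'   the RV-centroid anchor (required when the mask has no label-3 voxels).
#' @return integer array of segment labels.
#' @export
aha_segmentation <- function(mask, geometry, voxel_size_um, anchor = NULL) {
  stopifnot(inherits(geometry, "prolate_geometry"))
  anchor <- resolve_anchor(mask, geometry, voxel_size_um, anchor)
  d <- dim(mask)
  lv <- which(mask == 1 | mask == 2)
  if (length(lv) == 0) stop("mask has no LV voxels (labels 1/2)", call. = FALSE)
  rc <- region_coords(lv, d, geometry, voxel_size_um, anchor)
  # apical cap: wall apical of the cavity tip (no cavity at that level)
  wb <- wall_boundaries(mask != 0, geometry, voxel_size_um)
  cav <- which(wb$endo)
  z_tip <- if (length(cav)) {
    min(region_coords(cav, d, geometry, voxel_size_um, anchor)$zeta)
  } else {
    min(rc$zeta)
  }
  z_base <- max(rc$zeta)
  seg <- integer(length(lv))
  cap <- rc$zeta < z_tip
  third <- pmin(floor((rc$zeta - z_tip) / ((z_base - z_tip) / 3)), 2) # 0 apical .. 2 basal
  th <- rc$theta
  sector6 <- function(th) {
    # 60-degree sectors; mid-septum (theta 0) on the boundary between the
    # anteroseptal and inferoseptal segments
    dplyr::case_when(
      th >= 0 & th < 60 ~ 2L,    # anteroseptal
      th >= -60 & th < 0 ~ 3L,   # inferoseptal
      th >= -120 & th < -60 ~ 4L, # inferior
      th < -120 ~ 5L,            # inferolateral
      th >= 120 ~ 5L,
      th >= 60 & th < 120 ~ 1L,  # anterior
      TRUE ~ 6L                  # anterolateral (handled below)
    )
  }
  s6 <- sector6(th)
  # anterolateral vs inferolateral split of the lateral 120 degrees
  s6[th >= 120 & th < 180] <- 6L
  s6[th >= -180 & th < -120] <- 5L
  sector4 <- dplyr::case_when(
    th >= -45 & th < 45 ~ 14L,   # apical septal
    th >= 45 & th < 135 ~ 13L,   # apical anterior
    th >= -135 & th < -45 ~ 15L, # apical inferior
    TRUE ~ 16L                   # apical lateral
  )
  seg[third == 2] <- s6[third == 2]           # basal 1..6
  seg[third == 1] <- s6[third == 1] + 6L      # mid 7..12
  seg[third == 0] <- sector4[third == 0]      # apical 13..16
  seg[cap] <- 0L
  out <- array(NA_integer_, d)
  out[lv] <- seg
  out
}

#' AHA segment display names
#' @return named character vector for labels 0..16.
#' @export
aha_segment_names <- function() {
  setNames(
    c("apical cap (excluded)",
      "basal anterior", "basal anteroseptal", "basal inferoseptal",
      "basal inferior", "basal inferolateral", "basal anterolateral",
      "mid anterior", "mid anteroseptal", "mid inferoseptal",
      "mid inferior", "mid inferolateral", "mid anterolateral",
      "apical anterior", "apical septal", "apical inferior", "apical lateral"),
    as.character(0:16)
  )
}

#' Wall sectors and apico-basal levels
#'
#' Assigns every wall voxel a circumferential sector — LV quadrants
#' (septal/anterior/lateral/posterior, anchored at the mid-septum) for labels
#' 1–2 and angular thirds (anterior/lateral/posterior) for the RV label 3 —
#' and marks three apico-basal level slabs centred at fractions of the
#' apex-base extent (default 25/50/75%, each `slab_slices` voxel layers
#' thick).
#'
#' @param mask label array (1 LV free wall, 2 septum, 3 RV free wall).
#' @param geometry a [prolate_geometry()].
#' @param voxel_size_um voxel size (µm).
#' @param anchor optional mid-septum direction (default: toward RV centroid).
#' @param level_fracs level-centre positions as fractions of the apex-base
#'   extent (apical to basal).
#' @param slab_slices slab thickness in voxel layers.
#' @return list with integer arrays `sector`, `level` (NA outside), and the
#'   name lookup vectors `sector_names`, `level_names`.
#' @export
define_walls_and_levels <- function(mask, geometry, voxel_size_um,
                                    anchor = NULL,
                                    level_fracs = c(0.25, 0.5, 0.75),
                                    slab_slices = 5) {
  stopifnot(inherits(geometry, "prolate_geometry"))
  anchor <- resolve_anchor(mask, geometry, voxel_size_um, anchor)
  d <- dim(mask)
  wall <- which(mask != 0)
  rc <- region_coords(wall, d, geometry, voxel_size_um, anchor)
  th <- rc$theta
  sector_names <- c("lv_septal", "lv_anterior", "lv_lateral", "lv_posterior",
                    "rv_anterior", "rv_lateral", "rv_posterior")
  sec <- integer(length(wall))
  is_lv <- mask[wall] %in% c(1, 2)
  sec[is_lv & th >= -45 & th < 45] <- 1L
  sec[is_lv & th >= 45 & th < 135] <- 2L
  sec[is_lv & (th >= 135 | th < -135)] <- 3L
  sec[is_lv & th >= -135 & th < -45] <- 4L
  is_rv <- mask[wall] == 3
  if (any(is_rv)) {
    q <- stats::quantile(th[is_rv], c(1 / 3, 2 / 3))
    sec[is_rv] <- ifelse(th[is_rv] >= q[2], 5L,
                         ifelse(th[is_rv] >= q[1], 6L, 7L))
  }
  level_names <- c("apical", "mid", "basal")
  z0 <- min(rc$zeta); z1 <- max(rc$zeta)
  half <- slab_slices * mean(voxel_size_um) / 2
  lev <- rep(NA_integer_, length(wall))
  for (k in seq_along(level_fracs)) {
    ctr <- z0 + level_fracs[k] * (z1 - z0)
    hit <- is.na(lev) & abs(rc$zeta - ctr) <= half
    lev[hit] <- k
  }
  sector <- array(NA_integer_, d); sector[wall] <- sec
  level <- array(NA_integer_, d); level[wall] <- lev
  list(sector = sector, level = level,
       sector_names = sector_names, level_names = level_names)
}
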