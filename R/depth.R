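#' Classify non-wall voxels into endocardial and epicardial sides
#'
#' Splits the background of a wall mask into a cavity-side (endocardial) and
#' an outside (epicardial) seed set by comparing each voxel's confocal
#' ellipsoid coordinate against the median over the wall — voxels inside the
#' mid-wall confocal surface seed the endocardial distance, the rest the
#' epicardial one.
#'
#' @param mask wall mask (non-zero = wall).
#' @param geometry a [prolate_geometry()].
#' @param voxel_size_um voxel size (µm), scalar or length 3.
#' @return list of logical arrays `endo` and `epi`.
#' @export
wall_boundaries <- function(mask, geometry, voxel_size_um) {
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  d <- dim(mask)
  pts <- grid_coords_um(d, voxel_size_um)
  pc <- prolate_coords(pts, geometry)
  u <- array(cosh(pc$lambda_p), d)
  wall <- mask != 0
  u_mid <- stats::median(u[wall])
  list(endo = (!wall) & (u < u_mid), epi = (!wall) & (u >= u_mid))
}

#' Normalised transmural depth of wall voxels
#'
#' Per-voxel normalised position across the wall,
#' `d = dist_endo / (dist_endo + dist_epi)` with Euclidean distance
#' transforms to the endocardial and epicardial boundary seeds: 0 at the
#' endocardium, 1 at the epicardium. With `septum_reverse = TRUE`, voxels of
#' the septal label run in the LV-endo to RV-endo direction instead
#' (`1 - d`), matching the convention that septal profiles start at the LV
#' side; the default keeps the common endo-to-epi direction, which on an
#' LV-centred shell is already LV-endo outward.
#'
#' @param mask wall mask; non-zero = wall. Label 2 is treated as septum when
#'   `septum_reverse = TRUE`.
#' @param geometry a [prolate_geometry()] used to split the background into
#'   endo/epi sides (see [wall_boundaries()]); alternatively pass explicit
#'   seeds via `boundaries`.
#' @param voxel_size_um voxel size (µm).
#' @param boundaries optional list with logical arrays `endo`, `epi`
#'   overriding the geometric classification.
#' @param septum_reverse flip the depth direction within label-2 voxels.
#' @return a `depth_map`: array `depth` (NA off-wall), plus the seed arrays.
#' @export
transmural_depth <- function(mask, geometry = NULL, voxel_size_um = NULL,
                             boundaries = NULL, septum_reverse = FALSE) {
  if (is.null(boundaries)) {
    if (is.null(geometry) || is.null(voxel_size_um)) {
      stop("supply either `boundaries` or both `geometry` and `voxel_size_um`",
           call. = FALSE)
    }
    boundaries <- wall_boundaries(mask, geometry, voxel_size_um)
  }
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  vs <- voxel_size_um %||% c(1, 1, 1)
  d <- dim(mask)
  if (!any(boundaries$endo) || !any(boundaries$epi)) {
    stop("wall is not closed: endo/epi boundary surfaces are ambiguous ",
         "(one of the seed sets is empty)", call. = FALSE)
  }
  de <- array(cpp_edt(as.logical(boundaries$endo), as.integer(d), vs), d)
  dp <- array(cpp_edt(as.logical(boundaries$epi), as.integer(d), vs), d)
  # distances run to background voxel centres; the tissue surface lies half a
  # voxel closer on both sides
  h <- mean(vs) / 2
  de <- pmax(de - h, 0)
  dp <- pmax(dp - h, 0)
  depth <- de / (de + dp)
  depth[mask == 0] <- NA_real_
  if (septum_reverse) {
    sep <- mask == 2
    depth[sep] <- 1 - depth[sep]
  }
  structure(list(depth = depth, endo = boundaries$endo, epi = boundaries$epi,
                 voxel_size_um = vs),
            class = "depth_map")
}
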