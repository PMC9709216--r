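#' Helical and intrusion angle maps from an orientation field
#'
#' Converts the per-voxel myocyte axis (tertiary structure-tensor
#' eigenvector) into the two standard orientation angles of the ventricular
#' wall, using the local prolate-spheroidal frame of the fitted LV ellipsoid:
#'
#' * helical angle `HA = asin(v . l_hat)` — the angle between the axis and
#'   the local radial–circumferential (short-axis) plane; positive axes climb
#'   toward the base;
#' * intrusion angle `IA = asin(v . r_hat)` — the angle between the axis and
#'   the local epicardial tangential plane; positive axes dive toward the
#'   epicardium.
#'
#' Axes are sign-free, so each eigenvector is first flipped to satisfy
#' `v . c_hat >= 0` (tie-break `v . l_hat >= 0`), which makes both angle
#' signs well defined. By default the literal vector-to-plane reading
#' (arcsin of the plane-normal component) is used; `method = "projected"`
#' instead takes `HA = atan2(v . l_hat, v . c_hat)` (and analogously for IA),
#' the in-plane projection variant.
#'
#' @param orient an `orientation_field` from [eigendecompose()].
#' @param geometry a [prolate_geometry()] (RV voxels are expressed in the
#'   same LV frame).
#' @param mask optional array restricting the output to myocardial voxels.
#' @param method `"arcsin"` (default) or `"projected"`.
#' @return an `angle_maps` object: arrays `ha`, `ia` (degrees, NA where
#'   invalid), logical `valid`, and `voxel_size_um`.
#' @export
compute_angles <- function(orient, geometry, mask = NULL,
                           method = c("arcsin", "projected")) {
  stopifnot(inherits(orient, "orientation_field"),
            inherits(geometry, "prolate_geometry"))
  method <- match.arg(method)
  d <- dim(orient$l1)
  valid <- orient$valid
  if (!is.null(mask)) valid <- valid & (mask != 0)
  idx <- which(valid)
  n <- prod(d)
  v <- cbind(orient$v3[idx], orient$v3[idx + n], orient$v3[idx + 2 * n])
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("tertiary eigenvectors are not unit-norm at valid voxels",
         call. = FALSE)
  }
  pts <- grid_coords_um(d, orient$voxel_size_um)[idx, , drop = FALSE]
  basis <- local_basis(pts, geometry, on_axis = "na")
  on_ax <- !is.finite(rowSums(basis$c_hat))
  ha_v <- ia_v <- rep(NA_real_, length(idx))
  if (method == "arcsin") {
    ang <- axes_to_angles(v, basis)
    ha_v <- ang$ha
    ia_v <- ang$ia
  } else {
    dc <- rowSums(v * basis$c_hat)
    dl <- rowSums(v * basis$l_hat)
    dr <- rowSums(v * basis$r_hat)
    s <- sign(dc); s[s == 0] <- sign(dl)[s == 0]; s[s == 0] <- 1
    dc <- dc * s; dl <- dl * s; dr <- dr * s
    ha_v <- rad2deg(atan2(dl, dc))
    ia_v <- rad2deg(atan2(dr, dc))
  }
  ha_v[on_ax] <- NA_real_
  ia_v[on_ax] <- NA_real_
  ha <- array(NA_real_, d); ia <- array(NA_real_, d)
  ha[idx] <- ha_v; ia[idx] <- ia_v
  valid[idx[on_ax]] <- FALSE
  structure(
    list(ha = ha, ia = ia, valid = valid,
         voxel_size_um = orient$voxel_size_um, method = method),
    class = "angle_maps"
  )
}
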