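#' Specification of a synthetic myocardial phantom
#'
#' Describes a synthetic volume emulating episcopic-microscopy data of the
#' compact ventricular wall: either a rectangular `slab` (trivial frame —
#' circumferential +x, longitudinal +y, radial +z) or a truncated
#' `prolate_shell` (an ellipsoidal LV-like wall). The wall bears a texture of
#' bright capsule-shaped rods aligned with a prescribed fiber field — a
#' linear transmural helical-angle law from `ha_endo_deg` at the endocardium
#' to `ha_epi_deg` at the epicardium plus a constant intrusion angle — with
#' optional axially-symmetric orientation noise of concentration `kappa`
#' (`Inf` = no noise, `0` = isotropic axes) and additive Gaussian intensity
#' noise.
#'
#' Defaults mimic an embryonic-heart regime: 2 µm isotropic voxels, a
#' 100 x 60 µm mid-wall ellipsoid with a wall a few tens of µm thick, and a
#' +60/-60 degree transmural helical-angle span. Rods are rendered as long
#' thin strands (240 x 6 µm by default) that curve along the prescribed
#' field: myocyte aggregates are continuous fibers many cell lengths long,
#' so free rod ends — which imprint spurious axial gradients — are rare in
#' tissue and kept rare in the phantom.
#'
#' @param shape voxels per axis (length 3).
#' @param voxel_size_um isotropic voxel size, µm.
#' @param geometry_kind `"slab"` or `"prolate_shell"`.
#' @param Ra_um,Rb_um mid-wall ellipsoid semi-axes, µm (shell only; Ra > Rb).
#' @param wall_lambda_range endo/epi bounds of the wall as multiples of the
#'   mid-wall prolate lambda.
#' @param base_truncation_mu basal cut of the shell, degrees of the
#'   longitudinal coordinate from the apex pole.
#' @param ha_endo_deg,ha_epi_deg endpoints of the linear transmural
#'   helical-angle law, degrees in \[-90, 90\].
#' @param ia_deg constant prescribed intrusion angle, degrees.
#' @param kappa orientation-noise concentration (>= 0; `Inf` disables noise).
#' @param rod_length_um,rod_radius_um rod texture dimensions, µm: the length
#'   of one strand-like myocyte aggregate and its capsule radius.
#' @param rod_density expected rod (strand) seed points per µm^3 of wall.
#' @param noise_sd additive Gaussian intensity noise (intensity units; rods
#'   have intensity ~0.8 over a 0.1 background).
#' @param seed RNG seed; identical spec + seed gives byte-identical phantoms.
#' @return a validated `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(128, 128, 128),
                         voxel_size_um = 2,
                         geometry_kind = c("prolate_shell", "slab"),
                         Ra_um = 100, Rb_um = 60,
                         wall_lambda_range = c(0.75, 1.25),
                         base_truncation_mu = 120,
                         ha_endo_deg = 60, ha_epi_deg = -60,
                         ia_deg = 0,
                         kappa = Inf,
                         rod_length_um = 240, rod_radius_um = 3,
                         rod_density = 1.8e-4,
                         noise_sd = 0.05,
                         seed = 1) {
  geometry_kind <- match.arg(geometry_kind)
  if (length(shape) != 3 || any(shape < 8) || any(shape != round(shape))) {
    stop_field("shape", "must be 3 integer extents >= 8")
  }
  if (length(voxel_size_um) != 1 || voxel_size_um <= 0) {
    stop_field("voxel_size_um", "must be a positive scalar")
  }
  if (geometry_kind == "prolate_shell") {
    if (!(Ra_um > Rb_um) || Rb_um <= 0) {
      stop_field("Ra_um", "shell needs Ra_um > Rb_um > 0 (Ra = Rb is a degenerate prolate frame)")
    }
    if (length(wall_lambda_range) != 2 ||
        !(0 < wall_lambda_range[1] && wall_lambda_range[1] < wall_lambda_range[2])) {
      stop_field("wall_lambda_range", "must be increasing positive bounds")
    }
    if (base_truncation_mu <= 10 || base_truncation_mu > 180) {
      stop_field("base_truncation_mu", "must be in (10, 180] degrees")
    }
  }
  for (nm in c("ha_endo_deg", "ha_epi_deg", "ia_deg")) {
    v <- get(nm)
    if (abs(v) > 90) stop_field(nm, "must lie in [-90, 90] degrees")
  }
  smax <- max(abs(sin(deg2rad(c(ha_endo_deg, ha_epi_deg)))))
  if (smax^2 + sin(deg2rad(ia_deg))^2 > 1) {
    stop_field("ia_deg", "sin^2(HA) + sin^2(IA) exceeds 1: no unit axis has these angles")
  }
  if (is.na(kappa) || kappa < 0) stop_field("kappa", "must be >= 0 (Inf allowed)")
  if (rod_length_um <= 0) stop_field("rod_length_um", "must be positive")
  if (rod_radius_um <= 0) stop_field("rod_radius_um", "must be positive")
  if (rod_density <= 0) stop_field("rod_density", "must be positive")
  if (noise_sd < 0) stop_field("noise_sd", "must be non-negative")
  structure(
    list(shape = as.integer(shape), voxel_size_um = voxel_size_um,
         geometry_kind = geometry_kind, Ra_um = Ra_um, Rb_um = Rb_um,
         wall_lambda_range = wall_lambda_range,
         base_truncation_mu = base_truncation_mu,
         ha_endo_deg = ha_endo_deg, ha_epi_deg = ha_epi_deg, ia_deg = ia_deg,
         kappa = kappa, rod_length_um = rod_length_um,
         rod_radius_um = rod_radius_um, rod_density = rod_density,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Unit axis with prescribed helical/intrusion angles in a local orthonormal
# frame: HA is recovered exactly as asin(axis . l_hat) and IA as
# asin(axis . r_hat). basis entries are n x 3 matrices.
axis_from_angles <- function(ha_deg, ia_deg, basis) {
  sh <- sin(deg2rad(ha_deg)); si <- sin(deg2rad(ia_deg))
  cc <- sqrt(pmax(1 - sh^2 - si^2, 0))
  basis$c_hat * cc + basis$l_hat * sh + basis$r_hat * si
}

# Helical/intrusion angles (degrees) of sign-free axes in a local frame.
# Sign rule: flip each axis so axis . c_hat >= 0 (tie-break: axis . l_hat >= 0).
axes_to_angles <- function(axes, basis) {
  dc <- rowSums(axes * basis$c_hat)
  dl <- rowSums(axes * basis$l_hat)
  s <- sign(dc)
  s[s == 0] <- sign(dl)[s == 0]
  s[s == 0] <- 1
  dl <- dl * s
  dr <- rowSums(axes * basis$r_hat) * s
  list(ha = rad2deg(asin(pmin(pmax(dl, -1), 1))),
       ia = rad2deg(asin(pmin(pmax(dr, -1), 1))))
}

new_truth_field <- function(dim, mask_idx, axes, ha, ia, depth, basis) {
  put <- function(v) {
    a <- array(NA_real_, dim)
    a[mask_idx] <- v
    a
  }
  axis4 <- array(NA_real_, c(dim, 3))
  n <- prod(dim)
  for (k in 1:3) axis4[mask_idx + (k - 1) * n] <- axes[, k]
  structure(
    list(axis = axis4, ha = put(ha), ia = put(ia), depth = put(depth),
         mask_idx = mask_idx, basis = basis, dim = dim),
    class = "truth_field"
  )
}

# Axes of a truth field as an n x 3 matrix over its wall voxels.
truth_axes_matrix <- function(truth) {
  n <- prod(truth$dim)
  cbind(truth$axis[truth$mask_idx],
        truth$axis[truth$mask_idx + n],
        truth$axis[truth$mask_idx + 2 * n])
}

#' Perturb a truth fiber field with axially-symmetric orientation noise
#'
#' Each axis is redrawn from an axially-symmetric distribution centred on the
#' original axis: a tangent-space Gaussian with standard deviation
#' \eqn{1/\sqrt{2\kappa}} per tangent component (dispersion is monotone
#' decreasing in `kappa`). `kappa = Inf` is the identity; `kappa = 0` draws
#' isotropically random axes. Stored helical/intrusion angles and the axis
#' array are updated consistently; depth is untouched.
#'
#' @param truth a `truth_field`.
#' @param kappa concentration parameter (>= 0, `Inf` allowed).
#' @param seed optional seed for this perturbation alone.
#' @return a `truth_field` with perturbed axes.
#' @export
perturb_axes <- function(truth, kappa, seed = NULL) {
  stopifnot(inherits(truth, "truth_field"), kappa >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.infinite(kappa)) return(truth)
  v <- truth_axes_matrix(truth)
  n <- nrow(v)
  if (kappa == 0) {
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    v <- cbind(r * cos(phi), r * sin(phi), z)
  } else {
    # orthonormal tangent pair at each axis
    ref <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
    swap <- abs(v[, 1]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    e1 <- normalize_rows(ref - v * rowSums(ref * v))
    e2 <- cbind(v[, 2] * e1[, 3] - v[, 3] * e1[, 2],
                v[, 3] * e1[, 1] - v[, 1] * e1[, 3],
                v[, 1] * e1[, 2] - v[, 2] * e1[, 1])
    sdv <- 1 / sqrt(2 * kappa)
    v <- normalize_rows(v + e1 * rnorm(n, 0, sdv) + e2 * rnorm(n, 0, sdv))
  }
  ang <- axes_to_angles(v, truth$basis)
  new_truth_field(truth$dim, truth$mask_idx, v, ang$ha, ang$ia,
                  truth$depth[truth$mask_idx], truth$basis)
}

# Rod texture: a Poisson number of rods seeded at uniformly random wall
# positions. Each rod is traced as a polyline that follows the local (possibly
# noisy) truth axis field — myocyte aggregates are strands curving with the
# wall, not straight pins — and rendered as overlapping capsule segments,
# max-composited over a dark background so overlaps stay edge-free.
render_rod_texture <- function(dim, voxel_size_um, mask_idx, axes, spec) {
  wall_um3 <- length(mask_idx) * voxel_size_um^3
  n_rods <- rpois(1, spec$rod_density * wall_um3)
  vol <- array(0.1, dim)
  if (n_rods > 0) {
    row_of <- array(0L, dim)
    row_of[mask_idx] <- seq_along(mask_idx)
    step_um <- max(spec$rod_radius_um, voxel_size_um)
    n_steps <- max(1L, ceiling(spec$rod_length_um / step_um))
    # strands may run a short way past the segmented wall (the tissue does not
    # end at the mask): their end caps then sit outside the mask and do not
    # imprint spurious axial gradients on wall voxels
    extend_max <- ceiling(16 / step_um)
    axis_at <- function(p_vox, prev) {
      # nearest-voxel field lookup, sign-aligned with the walk direction
      i <- round(p_vox) + 1
      if (any(i < 1) || any(i > dim)) return(NULL) # left the volume
      r <- row_of[i[1], i[2], i[3]]
      if (r == 0L) return(NA) # outside the wall: keep the previous direction
      a <- axes[r, ]
      if (sum(a * prev) < 0) a <- -a
      a
    }
    pick <- sample.int(length(mask_idx), n_rods, replace = TRUE)
    starts <- arrayInd(mask_idx[pick], dim) - 1 +
      matrix(runif(3 * n_rods, -0.5, 0.5), ncol = 3)
    seg_p <- vector("list", n_rods)
    step_vox <- step_um / voxel_size_um
    for (r in seq_len(n_rods)) {
      a0 <- axes[pick[r], ]
      walk <- function(dir) {
        p <- starts[r, ]
        a <- a0 * dir
        out <- list()
        n_out <- 0L
        for (s in seq_len(ceiling(n_steps / 2) + extend_max)) {
          a_new <- axis_at(p, a)
          if (is.null(a_new)) break
          if (length(a_new) == 1 && is.na(a_new)) {
            n_out <- n_out + 1L
            if (n_out > extend_max) break
            a_new <- a
          } else if (s > ceiling(n_steps / 2)) {
            break # nominal length reached and back inside the wall
          } else {
            n_out <- 0L
          }
          p <- p + a_new * step_vox
          a <- a_new
          out[[s]] <- p
        }
        out
      }
      fwd <- walk(1)
      bwd <- walk(-1)
      seg_p[[r]] <- rbind(
        do.call(rbind, rev(bwd)),
        matrix(starts[r, ], nrow = 1),
        do.call(rbind, fwd)
      )
    }
    # consecutive in-order path points -> capsule segments (pooled)
    ctrs <- list(); dirs <- list()
    for (r in seq_len(n_rods)) {
      pts <- seg_p[[r]]
      if (nrow(pts) < 2) {
        ctrs[[r]] <- pts
        dirs[[r]] <- matrix(axes[pick[r], ], nrow = 1)
        next
      }
      d <- diff(pts)
      ctrs[[r]] <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
      dirs[[r]] <- normalize_rows(d)
    }
    centres <- do.call(rbind, ctrs)
    directions <- do.call(rbind, dirs)
    keep <- is.finite(rowSums(directions))
    vol <- array(
      cpp_paint_capsules(as.double(vol), as.integer(dim),
                         centres[keep, , drop = FALSE],
                         directions[keep, , drop = FALSE],
                         half_len = 0.5 * step_vox,
                         radius = spec$rod_radius_um / voxel_size_um,
                         intensity = 0.9),
      dim
    )
  }
  if (spec$noise_sd > 0) {
    vol <- vol + array(rnorm(prod(dim), 0, spec$noise_sd), dim)
  }
  vol
}

#' Generate a rectangular slab phantom
#'
#' A wall slab with a uniform fiber axis at helical angle `ha_endo_deg` and
#' intrusion angle `ia_deg` in the trivial frame (circumferential = +x,
#' longitudinal = +y, radial = +z), textured with rods and intensity noise.
#' The mask (label 1) excludes a 2-voxel border. Normalised depth runs along
#' +z.
#'
#' @param spec a [phantom_spec()] with `geometry_kind = "slab"`.
#' @return list with `volume` ([image_volume()]), `mask` (integer array) and
#'   `truth` (`truth_field`).
#' @export
make_slab_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry_kind != "slab") {
    stop_field("geometry_kind", "must be 'slab' for make_slab_phantom()")
  }
  set.seed(spec$seed)
  d <- spec$shape
  mask <- array(0L, d)
  mask[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- 1L
  idx <- which(mask == 1L)
  n <- length(idx)
  basis <- list(
    c_hat = matrix(rep(c(1, 0, 0), each = n), ncol = 3),
    l_hat = matrix(rep(c(0, 1, 0), each = n), ncol = 3),
    r_hat = matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  )
  axes <- axis_from_angles(rep(spec$ha_endo_deg, n), rep(spec$ia_deg, n), basis)
  kz <- arrayInd(idx, d)[, 3]
  depth <- (kz - 3) / (d[3] - 5)
  ang <- axes_to_angles(axes, basis)
  truth <- new_truth_field(d, idx, axes, ang$ha, ang$ia, depth, basis)
  if (!is.infinite(spec$kappa)) truth <- perturb_axes(truth, spec$kappa)
  vol <- render_rod_texture(d, spec$voxel_size_um, idx,
                            truth_axes_matrix(truth), spec)
  list(volume = image_volume(vol, spec$voxel_size_um), mask = mask,
       truth = truth)
}

#' Generate a truncated prolate-shell phantom
#'
#' An LV-like ellipsoidal wall: voxels whose prolate transmural coordinate
#' falls between the endo and epi bounds and whose longitudinal coordinate is
#' apical of the basal cut. The fiber field follows the linear transmural
#' helical-angle law `HA(d) = ha_endo + (ha_epi - ha_endo) d` (d = normalised
#' depth) with constant intrusion angle, expressed in the analytic local
#' prolate frame, optionally degraded by orientation noise, and rendered as a
#' rod texture.
#'
#' Labels: 1 = LV free wall, and with `label_sectors = TRUE` (default) a
#' septal sector (label 2, circumferential angle in \[-30, 30) degrees from
#' the reference direction) and an adjacent RV-like sector (label 3,
#' \[-90, -30)) are relabelled so regional operations are exercisable.
#'
#' @param spec a [phantom_spec()] with `geometry_kind = "prolate_shell"`.
#' @param label_sectors relabel septum/RV-like sectors (see above).
#' @return list with `volume`, `mask`, `truth` and `geometry` (the true
#'   [prolate_geometry()]).
#' @export
make_shell_phantom <- function(spec, label_sectors = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$geometry_kind != "prolate_shell") {
    stop_field("geometry_kind", "must be 'prolate_shell' for make_shell_phantom()")
  }
  set.seed(spec$seed)
  d <- spec$shape
  vs <- spec$voxel_size_um
  centre <- (d - 1) * vs / 2
  geom <- prolate_geometry(centre, c(0, 0, 1), spec$Ra_um, spec$Rb_um)
  lam_endo <- spec$wall_lambda_range[1] * geom$lambda_mid
  lam_epi <- spec$wall_lambda_range[2] * geom$lambda_mid
  thick_um <- min(
    geom$f * (cosh(lam_epi) - cosh(lam_endo)),   # apex-pole thickness
    geom$f * (sinh(lam_epi) - sinh(lam_endo))    # equatorial thickness
  )
  if (thick_um / vs < 3) {
    stop(sprintf(
      "wall is %.1f µm (< 3 voxels) thick somewhere: transmural profiles unresolvable",
      thick_um), call. = FALSE)
  }
  pts <- grid_coords_um(d, rep(vs, 3))
  pc <- prolate_coords(pts, geom)
  mu_max <- deg2rad(spec$base_truncation_mu)
  inwall <- pc$lambda_p >= lam_endo & pc$lambda_p <= lam_epi & pc$mu <= mu_max
  mask <- array(0L, d)
  mask[inwall] <- 1L
  if (label_sectors) {
    th <- rad2deg(pc$theta)
    mask[inwall & th >= -30 & th < 30] <- 2L
    mask[inwall & th >= -90 & th < -30] <- 3L
  }
  idx <- which(mask != 0L)
  basis <- local_basis(pts[idx, , drop = FALSE], geom, on_axis = "na")
  ok <- is.finite(rowSums(basis$c_hat)) # drop on-axis voxels (theta undefined)
  if (!all(ok)) {
    mask[idx[!ok]] <- 0L
    idx <- idx[ok]
    basis <- lapply(basis, function(m) m[ok, , drop = FALSE])
  }
  depth <- (pc$lambda_p[idx] - lam_endo) / (lam_epi - lam_endo)
  ha <- spec$ha_endo_deg + (spec$ha_epi_deg - spec$ha_endo_deg) * depth
  axes <- axis_from_angles(ha, rep(spec$ia_deg, length(idx)), basis)
  truth <- new_truth_field(d, idx, axes, ha,
                           rep(spec$ia_deg, length(idx)), depth, basis)
  if (!is.infinite(spec$kappa)) truth <- perturb_axes(truth, spec$kappa)
  vol <- render_rod_texture(d, vs, idx, truth_axes_matrix(truth), spec)
  list(volume = image_volume(vol, vs), mask = mask, truth = truth,
       geometry = geom)
}
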