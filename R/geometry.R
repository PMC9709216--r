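#' Semi-foci distance of a prolate spheroid
#'
#' \eqn{f = \sqrt{R_a^2 - R_b^2}} for an ellipsoid with major semi-axis
#' \eqn{R_a} and minor semi-axis \eqn{R_b}. \eqn{f = 0} (a sphere) makes the
#' prolate frame degenerate and is flagged by downstream constructors.
#'
#' @param Ra major semi-axis (µm).
#' @param Rb minor semi-axis (µm).
#' @return semi-foci distance in µm.
#' @export
semi_foci <- function(Ra, Rb) {
  if (any(Rb <= 0) || any(Ra <= 0)) stop_field("Ra/Rb", "must be positive")
  if (any(Rb > Ra)) stop_field("Rb", "must not exceed Ra")
  sqrt(Ra^2 - Rb^2)
}

#' Prolate-spheroidal LV geometry
#'
#' Defines the left-ventricular reference frame: ellipsoid centre, unit long
#' axis oriented apex-to-base, mid-wall semi-axes Ra > Rb, and the semi-foci
#' distance f. Transverse reference axes (for the circumferential angle
#' \eqn{\theta}) are fixed deterministically from the long axis.
#'
#' @param centre ellipsoid centre, µm (length 3).
#' @param long_axis apex-to-base direction (length 3; normalised internally).
#' @param Ra,Rb mid-wall major/minor semi-axes, µm (Ra > Rb).
#' @return a `prolate_geometry` object.
#' @export
prolate_geometry <- function(centre, long_axis, Ra, Rb) {
  if (Ra <= Rb) {
    stop_field("Ra", "must exceed Rb (a sphere has no prolate frame)")
  }
  u <- long_axis / sqrt(sum(long_axis^2))
  # deterministic transverse pair: project world x (or y when near-parallel)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1]) # u x e1
  f <- semi_foci(Ra, Rb)
  structure(
    list(centre = as.double(centre), long_axis = u, e1 = e1, e2 = e2,
         Ra = Ra, Rb = Rb, f = f, lambda_mid = acosh(Ra / f)),
    class = "prolate_geometry"
  )
}

#' @export
print.prolate_geometry <- function(x, ...) {
  cat(sprintf(
    "<prolate_geometry> centre (%s) µm, Ra %.1f, Rb %.1f, f %.1f µm\n",
    paste(signif(x$centre, 4), collapse = ", "), x$Ra, x$Rb, x$f))
  invisible(x)
}

#' Prolate-spheroidal coordinates of points
#'
#' Maps Cartesian µm positions into the LV prolate frame: transmural
#' \eqn{\lambda_p} (level sets are confocal ellipsoids), longitudinal
#' \eqn{\mu \in [0, \pi]} (0 at the apex pole) and circumferential
#' \eqn{\theta \in (-\pi, \pi]}.
#'
#' @param points n x 3 matrix of µm positions.
#' @param geometry a [prolate_geometry()].
#' @return tibble with columns `lambda_p`, `mu`, `theta`, `rho` (distance from
#'   the long axis, µm) and `zeta` (signed position along the long axis from
#'   the centre, apex negative).
#' @export
prolate_coords <- function(points, geometry) {
  stopifnot(inherits(geometry, "prolate_geometry"))
  p <- sweep(matrix(points, ncol = 3), 2, geometry$centre)
  zeta <- drop(p %*% geometry$long_axis)
  px <- drop(p %*% geometry$e1)
  py <- drop(p %*% geometry$e2)
  rho <- sqrt(px^2 + py^2)
  f <- geometry$f
  d_base <- sqrt(rho^2 + (zeta - f)^2) # focus on the basal side
  d_apex <- sqrt(rho^2 + (zeta + f)^2)
  u <- pmax((d_base + d_apex) / (2 * f), 1)
  cmu <- pmin(pmax((d_apex - d_base) / (2 * f), -1), 1)
  tibble::tibble(
    lambda_p = acosh(u),
    mu = acos(-cmu), # mu = 0 at the apex pole (zeta = -f cosh(l))
    theta = atan2(py, px),
    rho = rho,
    zeta = zeta
  )
}

#' Cartesian position from prolate coordinates
#' @param lambda_p,mu,theta prolate coordinates (vectors of equal length).
#' @param geometry a [prolate_geometry()].
#' @return n x 3 matrix of µm positions.
#' @export
prolate_to_cartesian <- function(lambda_p, mu, theta, geometry) {
  f <- geometry$f
  rho <- f * sinh(lambda_p) * sin(mu)
  zeta <- -f * cosh(lambda_p) * cos(mu)
  px <- rho * cos(theta)
  py <- rho * sin(theta)
  sweep(
    outer(px, geometry$e1) + outer(py, geometry$e2) +
      outer(zeta, geometry$long_axis),
    2, geometry$centre, `+`
  )
}

#' Local radial/circumferential/longitudinal basis at points
#'
#' Unit tangent vectors of the prolate frame at each point:
#' \eqn{\hat r} along increasing \eqn{\lambda_p} (endo to epi),
#' \eqn{\hat c} along increasing \eqn{\theta} (circumferential),
#' \eqn{\hat l} along increasing \eqn{\mu} (apex to base).
#' The triad is orthonormal and right-handed with
#' \eqn{\hat c \times \hat l = \hat r}. Points on the long axis have no
#' defined \eqn{\theta} and are rejected (or NA-flagged with
#' `on_axis = "na"`).
#'
#' @param points n x 3 matrix of µm positions.
#' @param geometry a [prolate_geometry()].
#' @param on_axis `"error"` or `"na"`.
#' @param tol_um distance from the axis below which a point counts as on-axis.
#' @return list of n x 3 matrices `r_hat`, `c_hat`, `l_hat`.
#' @export
local_basis <- function(points, geometry, on_axis = c("error", "na"),
                        tol_um = 1e-9) {
  on_axis <- match.arg(on_axis)
  pc <- prolate_coords(points, geometry)
  bad <- pc$rho <= tol_um
  if (any(bad) && on_axis == "error") {
    stop("point(s) on the long axis: circumferential direction undefined",
         call. = FALSE)
  }
  u <- geometry$long_axis
  p <- sweep(matrix(points, ncol = 3), 2, geometry$centre)
  px <- drop(p %*% geometry$e1)
  py <- drop(p %*% geometry$e2)
  rho_hat <- (outer(px, geometry$e1) + outer(py, geometry$e2)) / pc$rho
  c_hat <- (outer(py, geometry$e1) * -1 + outer(px, geometry$e2)) / pc$rho
  # in-plane (rho, zeta) components of the lambda/mu tangents
  cl <- cosh(pc$lambda_p); sl <- sinh(pc$lambda_p)
  cm <- cos(pc$mu); sm <- sin(pc$mu)
  r_rho <- cl * sm; r_zeta <- -sl * cm
  l_rho <- sl * cm; l_zeta <- cl * sm
  rn <- sqrt(r_rho^2 + r_zeta^2)
  r_hat <- rho_hat * (r_rho / rn) + outer(r_zeta / rn, u)
  l_hat <- rho_hat * (l_rho / rn) + outer(l_zeta / rn, u)
  if (any(bad)) {
    r_hat[bad, ] <- NA_real_; c_hat[bad, ] <- NA_real_; l_hat[bad, ] <- NA_real_
  }
  list(r_hat = r_hat, c_hat = c_hat, l_hat = l_hat)
}

#' Fit the LV prolate ellipsoid to a wall mask
#'
#' Estimates the LV reference frame from the segmented compact wall: centroid
#' and principal axis of the voxel cloud, apex/base disambiguation by the
#' myocardial cross-section area at the two axis ends (the base, being an open
#' ring at the basal truncation, is larger), then least-squares fitting of
#' \eqn{a\zeta^2 + b\zeta + c\rho^2 + d = 1} over wall voxels, giving the
#' on-axis centre correction and the semi-axes. With `refine = TRUE` the fit
#' is repeated on the mid-wall shell (normalised depth 0.35–0.65) computed
#' from the initial geometry, which removes the endo/epi thickness bias.
#'
#' @param mask logical/integer 3D array; non-zero marks wall voxels to use
#'   (pass LV labels only when RV voxels are present).
#' @param voxel_size_um voxel size (µm), scalar or length 3.
#' @param refine refit on the mid-wall shell (default TRUE).
#' @param min_voxels minimum wall voxel count (default 1000).
#' @return a [prolate_geometry()].
#' @export
fit_lv_ellipsoid <- function(mask, voxel_size_um, refine = TRUE,
                             min_voxels = 1000) {
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  idx <- which(mask != 0)
  if (length(idx) < min_voxels) {
    stop(sprintf("mask has %d wall voxels; at least %d required",
                 length(idx), min_voxels), call. = FALSE)
  }
  d <- dim(mask)
  co <- arrayInd(idx, d)
  pts <- sweep(co - 1, 2, voxel_size_um, `*`)
  geom <- fit_ellipsoid_points(pts)
  if (refine) {
    dm <- tryCatch(
      transmural_depth(mask, geom, voxel_size_um),
      error = function(e) NULL
    )
    if (!is.null(dm)) {
      dmid <- dm$depth[idx]
      sel <- !is.na(dmid) & dmid >= 0.35 & dmid <= 0.65
      if (sum(sel) >= min_voxels / 4) {
        # centre and axis are well determined by the full-wall fit; the
        # mid-wall shell (EDT depth 0.35-0.65) then pins the semi-axes free
        # of endo/epi thickness bias
        pc <- sweep(pts[sel, , drop = FALSE], 2, geom$centre)
        zeta <- drop(pc %*% geom$long_axis)
        rho2 <- rowSums(pc^2) - zeta^2
        X <- cbind(zeta^2, rho2)
        cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, rep(1, nrow(X)))),
                       error = function(e) NULL)
        if (!is.null(cf) && all(is.finite(cf)) && all(cf > 0) &&
            cf[1] < cf[2] * (1 - 1e-6)) {
          geom <- prolate_geometry(geom$centre, geom$long_axis,
                                   Ra = 1 / sqrt(cf[1]), Rb = 1 / sqrt(cf[2]))
        }
      }
    }
  }
  geom
}

# Quadric fit about a candidate axis u with a free centre: iterates the
# linearised model 1 = a*zeta^2 + b*zeta + c*rho^2 + d*px + e*py about the
# running centre (b, d, e vanish at convergence, so Ra = 1/sqrt(a),
# Rb = 1/sqrt(c)). Returns NULL when u yields no valid prolate ellipsoid.
quadric_fit_axis <- function(pts, u, centre, n_iter = 4) {
  # orthonormal transverse pair for the centre offsets
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  fit <- NULL
  for (it in seq_len(n_iter)) {
    pc <- sweep(pts, 2, centre)
    zeta <- drop(pc %*% u)
    px <- drop(pc %*% e1)
    py <- drop(pc %*% e2)
    rho2 <- px^2 + py^2
    if (sd(rho2) == 0 || sd(zeta) == 0) return(NULL)
    X <- cbind(zeta^2, zeta, rho2, px, py)
    cf <- tryCatch(qr.solve(crossprod(X), crossprod(X, rep(1, nrow(X)))),
                   error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    a <- cf[1]; cc <- cf[3]
    if (!is.finite(a) || !is.finite(cc) || a <= 0 || cc <= 0) return(NULL)
    centre <- centre + (-cf[2] / (2 * a)) * u +
      (-cf[4] / (2 * cc)) * e1 + (-cf[5] / (2 * cc)) * e2
    fit <- list(a = a, c = cc, rss = mean((drop(X %*% cf) - 1)^2))
  }
  Ra <- 1 / sqrt(fit$a)
  Rb <- 1 / sqrt(fit$c)
  if (Ra <= Rb * (1 + 1e-6)) return(NULL) # spherical/oblate: no prolate frame
  list(u = u, centre = centre, Ra = Ra, Rb = Rb, rss = fit$rss)
}

fit_ellipsoid_points <- function(all_pts) {
  # deterministic stride subsample keeps the search cheap on large walls
  pts <- if (nrow(all_pts) > 30000) {
    all_pts[unique(round(seq(1, nrow(all_pts), length.out = 30000))), ,
            drop = FALSE]
  } else all_pts
  ctr0 <- colMeans(pts)
  pc <- sweep(pts, 2, ctr0)
  ev <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)
  # a truncated shell's second moments do not single out the symmetry axis
  # reliably; try each principal direction and keep the best-fitting quadric
  cands <- purrr::compact(lapply(1:3, function(k) {
    quadric_fit_axis(pts, ev$vectors[, k], ctr0)
  }))
  if (length(cands) == 0) {
    stop("ellipsoid fit failed: wall mask is not a prolate ellipsoidal shell ",
         "(degenerate or spherical voxel cloud)", call. = FALSE)
  }
  best <- cands[[which.min(vapply(cands, `[[`, 0, "rss"))]]
  # refine the axis orientation: minimise the quadric residual over small
  # rotations of u (masks missing a sector tilt the principal directions)
  ref <- if (abs(best$u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- ref - sum(ref * best$u) * best$u
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(best$u[2] * b1[3] - best$u[3] * b1[2],
          best$u[3] * b1[1] - best$u[1] * b1[3],
          best$u[1] * b1[2] - best$u[2] * b1[1])
  obj <- function(th) {
    u <- best$u + th[1] * b1 + th[2] * b2
    u <- u / sqrt(sum(u^2))
    f <- quadric_fit_axis(pts, u, best$centre)
    if (is.null(f)) return(1e6)
    f$rss
  }
  op <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                     control = list(maxit = 60, reltol = 1e-6))
  u <- best$u + op$par[1] * b1 + op$par[2] * b2
  u <- u / sqrt(sum(u^2))
  best <- quadric_fit_axis(all_pts, u, best$centre) %||% best
  u <- best$u
  # apex/base: compare myocardial cross-section area in the extreme 10% slabs;
  # the basal (truncated, open-ring) end subtends more voxels per unit length
  t_along <- drop(sweep(pts, 2, best$centre) %*% u)
  rng <- range(t_along)
  w <- diff(rng) * 0.1
  if (sum(t_along <= rng[1] + w) > sum(t_along >= rng[2] - w)) u <- -u
  prolate_geometry(centre = best$centre, long_axis = u,
                   Ra = best$Ra, Rb = best$Rb)
}
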