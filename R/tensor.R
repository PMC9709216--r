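#' Central-difference intensity gradient of a volume
#'
#' Computes the per-voxel image gradient with central differences in the
#' interior and one-sided differences at the image border (border voxels are
#' flagged). Gradients are in intensity units per voxel; the volume must be
#' isotropic so that gradient *direction* is geometrically meaningful —
#' resample first with [resample_isotropic()] otherwise.
#'
#' @param volume an isotropic [image_volume()].
#' @param sigma_vox Gaussian pre-smoothing in voxels (0 disables); applied to
#'   the intensities before differentiation.
#' @return a `gradient_field`: list of arrays `gx`, `gy`, `gz`, logical
#'   `interior` (FALSE at one-sided border voxels) and `voxel_size_um`.
#' @export
compute_gradient <- function(volume, sigma_vox = 0) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is_isotropic(volume)) {
    stop("volume has anisotropic voxels; run resample_isotropic() first",
         call. = FALSE)
  }
  if (sigma_vox > 0) volume <- gaussian_smooth(volume, sigma_vox)
  v <- volume$values
  d <- dim(v)
  diff_axis <- function(axis) {
    n <- d[axis]
    if (n < 2) return(array(0, d))
    idx_p <- pmin(seq_len(n) + 1L, n)
    idx_m <- pmax(seq_len(n) - 1L, 1L)
    den <- (idx_p - idx_m) # 2 interior, 1 at the two border planes
    sel <- function(i) switch(axis,
      v[i, , , drop = FALSE], v[, i, , drop = FALSE], v[, , i, drop = FALSE])
    g <- sel(idx_p) - sel(idx_m)
    sweep_den <- switch(axis,
      array(rep(den, times = prod(d[2:3])), d),
      aperm(array(rep(den, times = prod(d[c(1, 3)])), d[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(rep(den, times = prod(d[1:2])), d[c(3, 1, 2)]), c(2, 3, 1)))
    array(g / sweep_den, d)
  }
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  structure(
    list(gx = diff_axis(1), gy = diff_axis(2), gz = diff_axis(3),
         interior = interior, voxel_size_um = volume$voxel_size_um),
    class = "gradient_field"
  )
}

#' Windowed structure tensor of a gradient field
#'
#' For every voxel, sums the outer products \eqn{g g^T} of the gradient
#' vectors over a cubic window centred on it, restricted to myocardial voxels
#' when a mask is given (no zero-padding leakage: sums near the mask boundary
#' simply run over fewer voxels).
#'
#' @param gradients a `gradient_field` from [compute_gradient()].
#' @param window odd window edge length in voxels. The default 7 spans more
#'   than one texture-element diameter at the default phantom scale, so the
#'   window samples both principal curvature directions of the bright-rod
#'   surfaces; a 3-voxel window (the voxel and its 26 cube neighbours) is the
#'   minimal choice and can be requested explicitly.
#' @param mask optional logical array of myocardial voxels; gradients outside
#'   it are excluded from every window sum.
#' @return a `tensor_field`: six component arrays (`xx`, `xy`, `xz`, `yy`,
#'   `yz`, `zz`), the per-voxel contributing count `n`, `window` and
#'   `voxel_size_um`.
#' @export
compute_structure_tensor <- function(gradients, window = 7, mask = NULL) {
  stopifnot(inherits(gradients, "gradient_field"))
  window <- assert_odd_window(window)
  d <- dim(gradients$gx)
  if (any(window > d)) {
    stop_field("window", "window exceeds the volume extent")
  }
  w <- if (is.null(mask)) array(1, d) else (mask != 0) * 1
  gx <- gradients$gx * w; gy <- gradients$gy * w; gz <- gradients$gz * w
  tf <- list(
    xx = box_sum(gx * gx, window),
    xy = box_sum(gx * gy, window),
    xz = box_sum(gx * gz, window),
    yy = box_sum(gy * gy, window),
    yz = box_sum(gy * gz, window),
    zz = box_sum(gz * gz, window),
    n = box_sum(w, window),
    window = window,
    voxel_size_um = gradients$voxel_size_um
  )
  structure(tf, class = "tensor_field")
}

#' Eigen-analysis of a structure tensor field
#'
#' Decomposes every in-mask tensor into eigenvalues sorted descending
#' (\eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0}) and the unit
#' eigenvector `v3` of the smallest eigenvalue — the direction of least
#' intensity variation, taken as the local myocyte long axis (sign-free).
#' A voxel is flagged invalid when its tensor is (near) zero or when
#' \eqn{\lambda_2 - \lambda_3 < \tau \lambda_1}: the axis is then not
#' distinguishable from its neighbours in the eigenvector plane.
#'
#' @param tensors a `tensor_field`.
#' @param mask optional logical array restricting which voxels are decomposed.
#' @param tau degeneracy threshold on the relative eigenvalue gap
#'   \eqn{(\lambda_2-\lambda_3)/\lambda_1}.
#' @param full_vectors also keep `v1`, `v2` (memory-heavy; only needed for
#'   diagnostics).
#' @return an `orientation_field`: arrays `l1`, `l2`, `l3`, a `[dim, 3]` array
#'   `v3`, logical `valid`, plus `voxel_size_um` (and `v1`, `v2` when
#'   requested).
#' @export
eigendecompose <- function(tensors, mask = NULL, tau = 0.05,
                           full_vectors = FALSE) {
  stopifnot(inherits(tensors, "tensor_field"))
  d <- dim(tensors$xx)
  compute <- if (is.null(mask)) array(TRUE, d) else (mask != 0)
  tr <- tensors$xx + tensors$yy + tensors$zz
  compute <- compute & (tr > 0)
  eg <- cpp_eig3_field(
    as.double(tensors$xx), as.double(tensors$xy), as.double(tensors$xz),
    as.double(tensors$yy), as.double(tensors$yz), as.double(tensors$zz),
    as.logical(compute), full_vectors
  )
  l1 <- array(eg$l1, d); l2 <- array(eg$l2, d); l3 <- array(eg$l3, d)
  # Sum-of-outer-products tensors are PSD up to roundoff; clamp tiny negatives
  neg_tol <- 1e-9 * tr + 1e-12 * max(tr)
  bad <- !is.na(l3) & (l3 < -neg_tol)
  if (any(bad)) {
    stop("structure tensor has substantially negative eigenvalues; ",
         "input tensors are not PSD", call. = FALSE)
  }
  l3[!is.na(l3) & l3 < 0] <- 0
  l2[!is.na(l2) & l2 < 0] <- 0
  valid <- compute & !is.na(l1) & ((l2 - l3) >= tau * l1) & (l1 > 0)
  v3 <- array(c(eg$v3x, eg$v3y, eg$v3z), dim = c(d, 3))
  out <- list(l1 = l1, l2 = l2, l3 = l3, v3 = v3, valid = valid,
              voxel_size_um = tensors$voxel_size_um, tau = tau)
  if (full_vectors) {
    out$v1 <- array(c(eg$v1x, eg$v1y, eg$v1z), dim = c(d, 3))
    out$v2 <- array(c(eg$v2x, eg$v2y, eg$v2z), dim = c(d, 3))
  }
  structure(out, class = "orientation_field")
}

#' Fractional anisotropy from structure-tensor eigenvalues
#'
#' \deqn{FA = \sqrt{3/2}\,
#'   \frac{\sqrt{(\lambda_1-\hat\lambda)^2 + (\lambda_2-\hat\lambda)^2 +
#'                (\lambda_3-\hat\lambda)^2}}
#'        {\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}}
#' with \eqn{\hat\lambda} the eigenvalue mean. FA is 0 for an isotropic
#' gradient distribution and 1 when all gradient energy lies along a single
#' direction; it is undefined (NaN) at zero-trace voxels.
#'
#' @param l1,l2,l3 eigenvalue vectors/arrays (sorted or not; the formula is
#'   symmetric), all non-negative.
#' @return FA values with the same shape as the input.
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(pmin(l1, l2, l3) < -1e-12 * pmax(l1, l2, l3, 1), na.rm = TRUE)) {
    stop("negative eigenvalues beyond tolerance", call. = FALSE)
  }
  lhat <- (l1 + l2 + l3) / 3
  num <- sqrt((l1 - lhat)^2 + (l2 - lhat)^2 + (l3 - lhat)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- sqrt(1.5) * num / den
  fa[!is.na(den) & den == 0] <- NaN
  fa
}

#' Per-voxel fractional anisotropy map
#'
#' @param orient an `orientation_field` from [eigendecompose()].
#' @return an `anisotropy_map`: array `fa` (NaN where undefined), array
#'   `lambda_hat`, and `voxel_size_um`.
#' @export
fractional_anisotropy <- function(orient) {
  stopifnot(inherits(orient, "orientation_field"))
  fa <- fa_from_eigenvalues(orient$l1, orient$l2, orient$l3)
  structure(
    list(fa = fa, lambda_hat = (orient$l1 + orient$l2 + orient$l3) / 3,
         voxel_size_um = orient$voxel_size_um),
    class = "anisotropy_map"
  )
}
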