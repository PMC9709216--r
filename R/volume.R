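#' 3D image volume with voxel-size metadata
#'
#' The basic container for grayscale microscopy data: a 3D numeric array
#' indexed `[x, y, z]` (z = original sectioning / apico-basal direction)
#' together with the per-axis voxel size in micrometres.
#'
#' @param values 3D numeric array of intensities.
#' @param voxel_size_um voxel size in µm; a single number (isotropic) or one
#'   value per axis.
#' @return An object of class `image_volume` with elements `values` and
#'   `voxel_size_um`.
#' @export
image_volume <- function(values, voxel_size_um) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop_field("values", "must be a 3D array")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_field("values", "must be finite")
  }
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop_field("voxel_size_um", "must be 3 positive numbers (µm)")
  }
  structure(
    list(values = values, voxel_size_um = as.double(voxel_size_um)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<image_volume> %d x %d x %d voxels, %s µm%s\n",
    d[1], d[2], d[3],
    paste(signif(x$voxel_size_um, 4), collapse = " x "),
    if (is_isotropic(x)) " (isotropic)" else " (anisotropic)"
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Is a volume's voxel grid isotropic?
#' @param volume an [image_volume()].
#' @param tol relative tolerance on voxel-size equality.
#' @return `TRUE` when all three voxel sizes agree within `tol`.
#' @export
is_isotropic <- function(volume, tol = 1e-6) {
  vs <- volume$voxel_size_um
  diff(range(vs)) <= tol * max(vs)
}

#' Resample a volume to an isotropic grid
#'
#' Trilinearly resamples intensities to the smallest of the three per-axis
#' voxel sizes, the usual preprocessing step before gradient-based orientation
#' analysis. Label volumes must be resampled with
#' [resample_labels()] (nearest-neighbour) instead.
#'
#' @param volume an [image_volume()].
#' @return an [image_volume()] with equal voxel sizes. Already-isotropic input
#'   is returned unchanged.
#' @export
resample_isotropic <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  if (is_isotropic(volume)) return(volume)
  target <- min(volume$voxel_size_um)
  vals <- resample_trilinear(volume$values, volume$voxel_size_um, target)
  image_volume(vals, target)
}

# Trilinear resampling of `arr` from spacing `vs` (length 3) to isotropic
# `target` spacing, preserving the physical field extent.
resample_trilinear <- function(arr, vs, target) {
  d <- dim(arr)
  nd <- pmax(2L, as.integer(round(d * vs / target)))
  # continuous source index (1-based) of each target sample, per axis
  src <- lapply(1:3, function(a) {
    s <- (seq_len(nd[a]) - 1) * target / vs[a] + 1
    pmin(pmax(s, 1), d[a])
  })
  i0 <- lapply(1:3, function(a) pmin(floor(src[[a]]), d[a] - 1))
  fr <- lapply(1:3, function(a) src[[a]] - i0[[a]])
  ix <- as.integer(i0[[1]]); iy <- as.integer(i0[[2]]); iz <- as.integer(i0[[3]])
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  out <- array(0, dim = nd)
  corner <- function(dx, dy, dz) {
    w <- outer(outer(if (dx) fx else 1 - fx, if (dy) fy else 1 - fy),
               if (dz) fz else 1 - fz)
    v <- arr[ix + dx, iy + dy, iz + dz, drop = FALSE]
    w * v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    out <- out + corner(dx, dy, dz)
  }
  out
}

#' Nearest-neighbour resampling for label/mask volumes
#' @param labels 3D integer/logical array.
#' @param voxel_size_um per-axis spacing of `labels` (µm).
#' @param target_um target isotropic spacing (µm).
#' @return resampled label array.
#' @export
resample_labels <- function(labels, voxel_size_um, target_um) {
  d <- dim(labels)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  nd <- pmax(2L, as.integer(round(d * voxel_size_um / target_um)))
  src <- lapply(1:3, function(a) {
    s <- round((seq_len(nd[a]) - 1) * target_um / voxel_size_um[a] + 1)
    as.integer(pmin(pmax(s, 1), d[a]))
  })
  labels[src[[1]], src[[2]], src[[3]], drop = FALSE]
}

#' Gaussian pre-smoothing of a volume
#'
#' Separable Gaussian filter (reflective boundaries), applied before gradient
#' computation to regularise the structure tensor. `sigma_vox = 0` is the
#' identity.
#'
#' @param volume an [image_volume()].
#' @param sigma_vox standard deviation in voxels.
#' @return smoothed [image_volume()].
#' @export
gaussian_smooth <- function(volume, sigma_vox = 1.0) {
  stopifnot(inherits(volume, "image_volume"), sigma_vox >= 0)
  if (sigma_vox == 0) return(volume)
  k <- gaussian_kernel_1d(sigma_vox)
  d <- dim(volume$values)
  sm <- cpp_conv_sep(as.double(volume$values), as.integer(d), k)
  image_volume(array(sm, d), volume$voxel_size_um)
}
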