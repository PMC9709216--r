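`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_odd_window <- function(window, name = "window") {
  if (length(window) != 1 || !is.finite(window) || window < 1 ||
      window != round(window) || window %% 2 == 0) {
    stop_field(name, "must be a single odd positive integer")
  }
  as.integer(window)
}

#' @noRd
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Row-wise normalisation of an n x 3 matrix; rows of zero norm become NA.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- NA_real_
  m / nrm
}

# Voxel-centre physical coordinates (µm) of all voxels of a grid, as an
# n x 3 matrix ordered like the flattened array (column-major).
grid_coords_um <- function(dim, voxel_size_um) {
  x <- (seq_len(dim[1]) - 1) * voxel_size_um[1]
  y <- (seq_len(dim[2]) - 1) * voxel_size_um[2]
  z <- (seq_len(dim[3]) - 1) * voxel_size_um[3]
  cbind(
    rep(x, times = dim[2] * dim[3]),
    rep(rep(y, each = dim[1]), times = dim[3]),
    rep(z, each = dim[1] * dim[2])
  )
}

# Box-filtered sum over a cubic window (edge windows clipped).
box_sum <- function(arr, window) {
  d <- dim(arr)
  out <- cpp_box_sum(as.double(arr), as.integer(d), as.integer(window))
  array(out, dim = d)
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}
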