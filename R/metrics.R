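#' Myocardial disarray index
#'
#' For every voxel, the axes (tertiary eigenvectors) of the valid myocardial
#' voxels in a cubic neighbourhood are pooled into the mean dyadic tensor
#' \eqn{\bar T = \langle v v^T \rangle} and the index is
#' \eqn{MDI = (3 \lambda_{max}(\bar T) - 1)/2}: 1 for perfectly aligned axes,
#' 0 for an isotropic axis distribution. The dyadic form makes the index
#' independent of eigenvector sign. The default 11-voxel window matches a
#' physical neighbourhood of `11 * voxel_size` µm per side (22 µm at 2 µm
#' voxels, 33 µm at 3 µm).
#'
#' An alternative reading of neighbourhood uniformity,
#' `method = "mean_dot"`, scores the mean absolute dot product between the
#' centre axis and its neighbours, rescaled from its isotropic expectation
#' (1/2) to the aligned value (1).
#'
#' @param orient an `orientation_field`.
#' @param mask optional myocardium mask; only in-mask valid voxels enter the
#'   neighbourhood statistics.
#' @param window odd neighbourhood edge length in voxels (default 11).
#' @param min_valid_frac minimum fraction of window voxels that must be valid
#'   myocardium for the index to be defined (default 0.5).
#' @param method `"dyadic"` (default) or `"mean_dot"`.
#' @return a `disarray_map`: array `mdi` (NA where undefined), `window`,
#'   `window_extent_um` (= window * voxel size) and `voxel_size_um`.
#' @export
compute_mdi <- function(orient, mask = NULL, window = 11,
                        min_valid_frac = 0.5,
                        method = c("dyadic", "mean_dot")) {
  stopifnot(inherits(orient, "orientation_field"))
  method <- match.arg(method)
  window <- assert_odd_window(window)
  if (window < 3) stop_field("window", "must be >= 3")
  d <- dim(orient$l1)
  valid <- orient$valid
  if (!is.null(mask)) valid <- valid & (mask != 0)
  n <- prod(d)
  w <- valid * 1
  vx <- ifelse(valid, orient$v3[seq_len(n)], 0)
  vy <- ifelse(valid, orient$v3[seq_len(n) + n], 0)
  vz <- ifelse(valid, orient$v3[seq_len(n) + 2 * n], 0)
  dim(vx) <- dim(vy) <- dim(vz) <- d
  cnt <- box_sum(array(w, d), window)
  sxx <- box_sum(vx * vx, window); sxy <- box_sum(vx * vy, window)
  sxz <- box_sum(vx * vz, window); syy <- box_sum(vy * vy, window)
  syz <- box_sum(vy * vz, window); szz <- box_sum(vz * vz, window)
  ok <- valid & (cnt >= min_valid_frac * window^3)
  if (method == "dyadic") {
    cs <- pmax(cnt, 1)
    eg <- cpp_eig3_field(
      as.double(sxx / cs), as.double(sxy / cs), as.double(sxz / cs),
      as.double(syy / cs), as.double(syz / cs), as.double(szz / cs),
      as.logical(ok), FALSE
    )
    mdi <- array((3 * eg$l1 - 1) / 2, d)
  } else {
    # mean |v_centre . v_j| does not distribute over window sums; direct pass
    mdi <- mean_dot_mdi(vx, vy, vz, valid, window)
  }
  mdi[!ok] <- NA_real_
  mdi[!is.na(mdi)] <- pmin(pmax(mdi[!is.na(mdi)], 0), 1)
  structure(
    list(mdi = mdi, window = window,
         window_extent_um = window * orient$voxel_size_um,
         voxel_size_um = orient$voxel_size_um),
    class = "disarray_map"
  )
}

# Direct neighbourhood pass for the mean-|dot| variant (small volumes only).
mean_dot_mdi <- function(vx, vy, vz, valid, window) {
  d <- dim(vx)
  h <- (window - 1) / 2
  out <- array(NA_real_, d)
  idx <- which(valid)
  co <- arrayInd(idx, d)
  for (r in seq_along(idx)) {
    i <- co[r, 1]; j <- co[r, 2]; k <- co[r, 3]
    xs <- max(1, i - h):min(d[1], i + h)
    ys <- max(1, j - h):min(d[2], j + h)
    zs <- max(1, k - h):min(d[3], k + h)
    sel <- valid[xs, ys, zs]
    if (!any(sel)) next
    dots <- abs(vx[xs, ys, zs][sel] * vx[i, j, k] +
                vy[xs, ys, zs][sel] * vy[i, j, k] +
                vz[xs, ys, zs][sel] * vz[i, j, k])
    out[i, j, k] <- 2 * mean(dots) - 1
  }
  out
}

#' Classify helical and intrusion angles into the standard bins
#'
#' Helical-angle classes: circumferential (|HA| <= 20 deg, boundary
#' inclusive), longitudinal-positive (HA > 20) and longitudinal-negative
#' (HA < -20). Intrusion-angle classes: |IA| <= 15, 15 < |IA| <= 45 and
#' |IA| > 45 degrees.
#'
#' @param angles an `angle_maps` object, or a list with numeric `ha`, `ia`.
#' @param region_mask optional logical/integer array selecting the region.
#' @param ha_threshold,ia_thresholds classification thresholds in degrees.
#' @return one-row tibble: `n`, `frac_circ`, `frac_long_pos`,
#'   `frac_long_neg`, `frac_ia_le15`, `frac_ia_15_45`, `frac_ia_gt45` (each
#'   triple sums to 1).
#' @export
classify_angles <- function(angles, region_mask = NULL, ha_threshold = 20,
                            ia_thresholds = c(15, 45)) {
  ha <- angles$ha
  ia <- angles$ia
  keep <- !is.na(ha) & !is.na(ia)
  if (!is.null(region_mask)) keep <- keep & (region_mask != 0)
  ha <- ha[keep]; ia <- ia[keep]
  if (length(ha) == 0) stop("empty region: no valid voxels", call. = FALSE)
  n <- length(ha)
  aia <- abs(ia)
  tibble::tibble(
    n = n,
    frac_circ = sum(abs(ha) <= ha_threshold) / n,
    frac_long_pos = sum(ha > ha_threshold) / n,
    frac_long_neg = sum(ha < -ha_threshold) / n,
    frac_ia_le15 = sum(aia <= ia_thresholds[1]) / n,
    frac_ia_15_45 = sum(aia > ia_thresholds[1] & aia <= ia_thresholds[2]) / n,
    frac_ia_gt45 = sum(aia > ia_thresholds[2]) / n
  )
}

#' Per-region summaries of orientation and organisation maps
#'
#' One tidy row per region: voxel count, mean/SD of FA and MDI, and the
#' helical/intrusion classification fractions.
#'
#' @param region_labels integer/factor 3D array (NA or 0 = outside any
#'   region).
#' @param fa optional `anisotropy_map` (or numeric array).
#' @param mdi optional `disarray_map` (or numeric array).
#' @param angles optional `angle_maps`.
#' @param region_names optional named character vector mapping label values
#'   to region names.
#' @return tibble with columns `region`, `n_voxels`, `mean_FA`, `sd_FA`,
#'   `mean_MDI`, `sd_MDI` and the six classification fractions.
#' @export
summarize_regions <- function(region_labels, fa = NULL, mdi = NULL,
                              angles = NULL, region_names = NULL) {
  fa_arr <- if (inherits(fa, "anisotropy_map")) fa$fa else fa
  mdi_arr <- if (inherits(mdi, "disarray_map")) mdi$mdi else mdi
  for (nm in c("fa_arr", "mdi_arr")) {
    a <- get(nm)
    if (!is.null(a) && !all(dim(a) == dim(region_labels))) {
      stop("map and region label shapes differ", call. = FALSE)
    }
  }
  labs <- sort(unique(region_labels[!is.na(region_labels) & region_labels != 0]))
  purrr::map_dfr(labs, function(lb) {
    sel <- !is.na(region_labels) & region_labels == lb
    row <- tibble::tibble(
      region = if (!is.null(region_names) && as.character(lb) %in% names(region_names))
        region_names[[as.character(lb)]] else as.character(lb),
      n_voxels = sum(sel)
    )
    row$mean_FA <- if (!is.null(fa_arr)) mean(fa_arr[sel], na.rm = TRUE) else NA_real_
    row$sd_FA <- if (!is.null(fa_arr)) sd(fa_arr[sel], na.rm = TRUE) else NA_real_
    row$mean_MDI <- if (!is.null(mdi_arr)) mean(mdi_arr[sel], na.rm = TRUE) else NA_real_
    row$sd_MDI <- if (!is.null(mdi_arr)) sd(mdi_arr[sel], na.rm = TRUE) else NA_real_
    if (!is.null(angles)) {
      cls <- tryCatch(classify_angles(angles, sel), error = function(e) NULL)
      if (!is.null(cls)) {
        row <- dplyr::bind_cols(row, dplyr::select(cls, -"n"))
        row$mean_HA <- mean(angles$ha[sel], na.rm = TRUE)
        row$mean_IA <- mean(angles$ia[sel], na.rm = TRUE)
      }
    }
    row
  })
}

#' Tidy per-region angle histograms
#'
#' 5-degree binned counts of HA and IA per region, in long format for
#' plotting (the region histogram figures of the pipeline report).
#'
#' @param angles an `angle_maps`.
#' @param region_labels integer/factor array (0/NA = outside).
#' @param bin_width bin width in degrees.
#' @return tibble with `region`, `angle_type`, `bin_lo`, `bin_hi`, `count`.
#' @export
region_histograms <- function(angles, region_labels, bin_width = 5) {
  breaks <- seq(-90, 90, by = bin_width)
  labs <- sort(unique(region_labels[!is.na(region_labels) & region_labels != 0]))
  purrr::map_dfr(labs, function(lb) {
    sel <- !is.na(region_labels) & region_labels == lb
    purrr::map_dfr(c(HA = "ha", IA = "ia"), function(fld) {
      v <- angles[[fld]][sel]
      v <- v[!is.na(v)]
      ct <- hist(v, breaks = breaks, plot = FALSE)$counts
      tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                     count = ct)
    }, .id = "angle_type") |>
      dplyr::mutate(region = as.character(lb), .before = 1)
  })
}
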