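#' Plot a z-slice of a per-voxel map
#'
#' Quick ggplot2 raster view of one slice of an FA, MDI, angle or depth map
#' (or any numeric 3D array).
#'
#' @param map an `anisotropy_map`, `disarray_map`, `angle_maps`, `depth_map`
#'   or numeric 3D array.
#' @param slice z index (default: middle slice).
#' @param what for `angle_maps`: `"ha"` or `"ia"`.
#' @return a ggplot object.
#' @export
plot_slice <- function(map, slice = NULL, what = "ha") {
  arr <- if (inherits(map, "anisotropy_map")) map$fa
    else if (inherits(map, "disarray_map")) map$mdi
    else if (inherits(map, "depth_map")) map$depth
    else if (inherits(map, "angle_maps")) map[[what]]
    else map
  d <- dim(arr)
  slice <- slice %||% (d[3] %/% 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(arr[, , slice])
  lab <- if (inherits(map, "angle_maps")) toupper(what)
    else if (inherits(map, "anisotropy_map")) "FA"
    else if (inherits(map, "disarray_map")) "MDI"
    else if (inherits(map, "depth_map")) "depth"
    else "value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", name = lab) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("slice z = %d", slice))
}

#' Bar chart of per-region summary metrics
#'
#' @param summary tibble from [summarize_regions()].
#' @param metric column to plot (default `mean_FA`).
#' @return a ggplot object.
#' @export
plot_region_summary <- function(summary, metric = "mean_FA") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$region, y = .data[[metric]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histograms of regional angle distributions
#'
#' @param hist_tbl tibble from [region_histograms()].
#' @return a ggplot object, faceted by region and angle type.
#' @export
plot_angle_histograms <- function(hist_tbl) {
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 4) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$region),
                        cols = ggplot2::vars(.data$angle_type)) +
    ggplot2::labs(x = "angle (degrees)", y = "voxels")
}
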