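#' Fit linear transmural angle profiles per wall sector and level
#'
#' Pools all valid voxels of each (sector, level) cell and fits the linear
#' law `angle = beta1 * depth + beta0` by ordinary least squares, separately
#' for the helical and intrusion angle. `beta1` is the transmural gradient in
#' degrees per normalised wall depth (0 endo, 1 epi) and `R^2` the linearity
#' coefficient (defined as 0 when the angle variance is 0). Cells with fewer
#' than `min_voxels` valid voxels are skipped and recorded.
#'
#' @param depth a `depth_map` from [transmural_depth()] (or a numeric array).
#' @param angles an `angle_maps` from [compute_angles()].
#' @param sectors list from [define_walls_and_levels()] (arrays `sector`,
#'   `level` plus name lookups).
#' @param min_voxels minimum voxels per cell (default 20).
#' @return a `transmural_fits` object; `tidy()` gives one row per fitted cell
#'   (`sector`, `level`, `angle_type`, `beta1_deg`, `beta0_deg`, `r2`, `n`),
#'   `glance()` an overall summary, and `autoplot()` profile panels. Skipped
#'   cells are listed in `$skipped`.
#' @export
fit_transmural_profile <- function(depth, angles, sectors, min_voxels = 20) {
  d_arr <- if (inherits(depth, "depth_map")) depth$depth else depth
  keep <- !is.na(d_arr) & !is.na(angles$ha) & !is.na(sectors$sector) &
    !is.na(sectors$level)
  idx <- which(keep)
  dat <- tibble::tibble(
    sector = sectors$sector_names[sectors$sector[idx]],
    level = sectors$level_names[sectors$level[idx]],
    depth = d_arr[idx],
    HA = angles$ha[idx],
    IA = angles$ia[idx]
  ) |>
    tidyr::pivot_longer(c("HA", "IA"), names_to = "angle_type",
                        values_to = "angle") |>
    dplyr::filter(!is.na(.data$angle))
  cells <- dat |>
    dplyr::group_by(.data$sector, .data$level, .data$angle_type) |>
    tidyr::nest() |>
    dplyr::ungroup()
  fit_one <- function(df) {
    if (nrow(df) < min_voxels) return(NULL)
    sst <- sum((df$angle - mean(df$angle))^2)
    if (sst == 0) {
      return(tibble::tibble(beta1_deg = 0, beta0_deg = df$angle[1], r2 = 0,
                            n = nrow(df)))
    }
    ft <- lm(angle ~ depth, data = df)
    ssr <- sum(ft$residuals^2)
    tibble::tibble(beta1_deg = coef(ft)[["depth"]],
                   beta0_deg = coef(ft)[["(Intercept)"]],
                   r2 = 1 - ssr / sst, n = nrow(df))
  }
  fitted <- purrr::map(cells$data, fit_one)
  ok <- !purrr::map_lgl(fitted, is.null)
  empty_fits <- tibble::tibble(
    sector = character(), level = character(), angle_type = character(),
    beta1_deg = double(), beta0_deg = double(), r2 = double(), n = integer()
  )
  fits <- if (any(ok)) {
    dplyr::bind_cols(
      dplyr::select(cells[ok, ], -"data"),
      dplyr::bind_rows(fitted[ok])
    )
  } else empty_fits
  skipped <- dplyr::select(cells[!ok, ], -"data") |>
    dplyr::mutate(n = purrr::map_int(cells$data[!ok], nrow))
  if (nrow(skipped)) {
    warning(sprintf("%d sector-level cell(s) skipped (< %d voxels)",
                    nrow(skipped), min_voxels), call. = FALSE)
  }
  structure(list(fits = fits, data = dat, skipped = skipped,
                 min_voxels = min_voxels),
            class = "transmural_fits")
}

#' @export
print.transmural_fits <- function(x, ...) {
  cat(sprintf("<transmural_fits> %d fitted cell(s), %d skipped\n",
              nrow(x$fits), nrow(x$skipped)))
  print(x$fits, n = 12)
  invisible(x)
}

#' @rdname fit_transmural_profile
#' @param x a `transmural_fits` object.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.transmural_fits <- function(x, ...) x$fits

#' @rdname fit_transmural_profile
#' @exportS3Method generics::glance
glance.transmural_fits <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$fits),
    n_skipped = nrow(x$skipped),
    n_voxels = if (nrow(x$fits)) sum(x$fits$n) else 0L,
    mean_r2 = if (nrow(x$fits)) mean(x$fits$r2) else NA_real_,
    min_r2 = if (nrow(x$fits)) min(x$fits$r2) else NA_real_
  )
}

#' @rdname fit_transmural_profile
#' @param object a `transmural_fits` object.
#' @param angle_type `"HA"`, `"IA"` or both.
#' @param max_points scatter points drawn per cell.
#' @param recentre shift each profile so the fitted zero-crossing of the
#'   angle sits at depth 0 (presentation transform only; fits are unchanged).
#' @exportS3Method ggplot2::autoplot
autoplot.transmural_fits <- function(object, angle_type = c("HA", "IA"),
                                     max_points = 500, recentre = FALSE,
                                     ...) {
  angle_type <- match.arg(angle_type, several.ok = TRUE)
  fits <- dplyr::filter(object$fits, .data$angle_type %in% !!angle_type)
  dat <- dplyr::filter(object$data, .data$angle_type %in% !!angle_type) |>
    dplyr::semi_join(fits, by = c("sector", "level", "angle_type")) |>
    dplyr::group_by(.data$sector, .data$level, .data$angle_type) |>
    dplyr::slice_sample(n = max_points) |>
    dplyr::ungroup()
  if (recentre) {
    shift <- fits |>
      dplyr::mutate(x0 = ifelse(.data$beta1_deg != 0,
                                -.data$beta0_deg / .data$beta1_deg, 0))
    dat <- dat |>
      dplyr::left_join(
        dplyr::select(shift, "sector", "level", "angle_type", "x0"),
        by = c("sector", "level", "angle_type")
      ) |>
      dplyr::mutate(depth = .data$depth - .data$x0)
    fits <- dplyr::mutate(shift, beta0_deg = 0)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$depth, y = .data$angle)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.4) +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$beta1_deg, intercept = .data$beta0_deg),
      colour = "red"
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$level),
      cols = ggplot2::vars(.data$sector, .data$angle_type)
    ) +
    ggplot2::labs(x = "normalised transmural depth (endo 0 - epi 1)",
                  y = "angle (degrees)")
}
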