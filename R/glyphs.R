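#' Export myocyte-axis glyphs as legacy VTK polydata
#'
#' Writes one line glyph per valid voxel of the selected z-slice(s): a
#' segment centred on the voxel, directed along the tertiary eigenvector
#' (myocyte long axis), carrying the helical angle as a cell scalar for
#' colour-coding in any VTK viewer.
#'
#' @param orient an `orientation_field`.
#' @param angles an `angle_maps` co-registered with it.
#' @param mask myocardium mask (non-zero = wall).
#' @param slices z-slice index or indices to export.
#' @param path output `.vtk` path.
#' @param length_um glyph length (µm); default 0.9 voxel.
#' @return `path` invisibly; the file holds exactly one `LINES` cell per
#'   exported voxel.
#' @export
export_glyphs <- function(orient, angles, mask, slices, path,
                          length_um = NULL) {
  stopifnot(inherits(orient, "orientation_field"),
            inherits(angles, "angle_maps"))
  d <- dim(orient$l1)
  vs <- orient$voxel_size_um
  sel <- array(FALSE, d)
  sel[, , slices] <- TRUE
  sel <- sel & orient$valid & (mask != 0) & !is.na(angles$ha)
  idx <- which(sel)
  if (length(idx) == 0) {
    stop("empty glyph selection: no valid voxels in the chosen slice(s)",
         call. = FALSE)
  }
  n <- length(idx)
  nn <- prod(d)
  v <- cbind(orient$v3[idx], orient$v3[idx + nn], orient$v3[idx + 2 * nn])
  ctr <- grid_coords_um(d, vs)[idx, , drop = FALSE]
  half <- (length_um %||% (0.9 * mean(vs))) / 2
  p0 <- ctr - half * v
  p1 <- ctr + half * v
  pts <- matrix(NA_real_, 2L * n, 3)
  pts[seq(1L, 2L * n, by = 2L), ] <- p0
  pts[seq(2L, 2L * n, by = 2L), ] <- p1
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c("# vtk DataFile Version 3.0",
               "myocyte axis glyphs (HA-coloured)",
               "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", 2L * n)), con)
  write(t(pts), con, ncolumns = 3)
  writeLines(sprintf("LINES %d %d", n, 3L * n), con)
  conn <- cbind(2L, seq.int(0L, 2L * n - 1L, by = 2L),
                seq.int(1L, 2L * n - 1L, by = 2L))
  write(t(conn), con, ncolumns = 3)
  writeLines(c(sprintf("CELL_DATA %d", n),
               "SCALARS HA float 1",
               "LOOKUP_TABLE default"), con)
  write(angles$ha[idx], con, ncolumns = 9)
  invisible(path)
}
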