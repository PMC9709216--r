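#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, with the defaults used
#' throughout the package. Serialises losslessly to YAML via
#' [save_config()] / [load_config()].
#'
#' @param volume_path,mask_path input files (NRRD/TIFF); may be NULL when
#'   volumes are passed to [run_pipeline()] directly.
#' @param voxel_size_um voxel size override for TIFF inputs.
#' @param smooth_sigma_vox Gaussian pre-smoothing before gradients (voxels).
#' @param tensor_window structure-tensor aggregation window (odd voxels).
#' @param tau eigen-degeneracy threshold (relative eigenvalue gap).
#' @param mdi_window disarray-index neighbourhood (odd voxels).
#' @param ha_threshold,ia_thresholds angle classification thresholds (deg).
#' @param level_fracs,slab_slices apico-basal level placement.
#' @param min_profile_voxels minimum voxels per profile cell.
#' @param septum_reverse run septal depth LV-endo to RV-endo.
#' @param angle_method `"arcsin"` or `"projected"` (see [compute_angles()]).
#' @param glyph_slices z-slices for glyph export (NULL = mid-slice).
#' @param output_dir report directory for [write_report()].
#' @param seed RNG seed recorded with the run.
#' @return a `pipeline_config` (named list).
#' @export
pipeline_config <- function(volume_path = NULL, mask_path = NULL,
                            voxel_size_um = NULL,
                            smooth_sigma_vox = 1.0,
                            tensor_window = 7,
                            tau = 0.05,
                            mdi_window = 11,
                            ha_threshold = 20,
                            ia_thresholds = c(15, 45),
                            level_fracs = c(0.25, 0.5, 0.75),
                            slab_slices = 5,
                            min_profile_voxels = 20,
                            septum_reverse = FALSE,
                            angle_method = "arcsin",
                            glyph_slices = NULL,
                            output_dir = NULL,
                            seed = 1L) {
  if (ha_threshold <= 0 || any(ia_thresholds <= 0)) {
    stop_field("thresholds", "must be positive degrees")
  }
  assert_odd_window(tensor_window, "tensor_window")
  assert_odd_window(mdi_window, "mdi_window")
  structure(
    list(volume_path = volume_path, mask_path = mask_path,
         voxel_size_um = voxel_size_um,
         smooth_sigma_vox = smooth_sigma_vox, tensor_window = tensor_window,
         tau = tau, mdi_window = mdi_window, ha_threshold = ha_threshold,
         ia_thresholds = ia_thresholds, level_fracs = level_fracs,
         slab_slices = slab_slices,
         min_profile_voxels = min_profile_voxels,
         septum_reverse = septum_reverse, angle_method = angle_method,
         glyph_slices = glyph_slices, output_dir = output_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full myoarchitecture analysis
#'
#' Executes, in order: isotropic resampling, Gaussian smoothing + gradients,
#' structure tensor, eigendecomposition, FA, LV ellipsoid fit, helical and
#' intrusion angles, MDI, transmural depth, wall sectors and levels, angle
#' classifications, transmural profile fits, and AHA 16-segment summaries.
#' Deterministic given (inputs, config).
#'
#' @param config a [pipeline_config()].
#' @param volume an [image_volume()]; read from `config$volume_path` if NULL.
#' @param mask a label array (1 LV free wall, 2 septum, 3 RV free wall); read
#'   from `config$mask_path` if NULL.
#' @param geometry optional [prolate_geometry()]; fitted from the LV labels
#'   if NULL.
#' @param anchor optional mid-septum anchor direction (needed when the mask
#'   has no RV label).
#' @param verbose log stage progress via `message()`.
#' @return a `pipeline_result` list: `orientation`, `fa`, `mdi`, `angles`,
#'   `depth`, `geometry`, `sectors`, `aha`, `fits`, and the tibbles
#'   `region_summary`, `aha_summary`, `classifications`, plus the `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), volume = NULL,
                         mask = NULL, geometry = NULL, anchor = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(volume)) {
    if (is.null(config$volume_path)) stop("no input volume", call. = FALSE)
    volume <- stage("read", read_volume(config$volume_path,
                                        config$voxel_size_um))
  }
  if (is.null(mask)) {
    if (is.null(config$mask_path)) stop("no input mask", call. = FALSE)
    mask <- stage("read", read_volume(config$mask_path)$values)
  }
  set.seed(config$seed)
  if (!is_isotropic(volume)) {
    say("resampling to isotropic voxels")
    target <- min(volume$voxel_size_um)
    mask <- stage("resample",
                  resample_labels(mask, volume$voxel_size_um, target))
    volume <- stage("resample", resample_isotropic(volume))
  }
  vs <- volume$voxel_size_um
  say("gradients + structure tensor (window %d, sigma %.2f)",
      config$tensor_window, config$smooth_sigma_vox)
  grad <- stage("gradient",
                compute_gradient(volume, sigma_vox = config$smooth_sigma_vox))
  tens <- stage("tensor",
                compute_structure_tensor(grad, config$tensor_window, mask))
  say("eigendecomposition")
  orient <- stage("eigen", eigendecompose(tens, mask, tau = config$tau))
  say("  valid axis voxels: %.1f%% of wall",
      100 * sum(orient$valid) / sum(mask != 0))
  fa <- stage("fa", fractional_anisotropy(orient))
  if (is.null(geometry)) {
    say("fitting LV prolate ellipsoid")
    geometry <- stage("geometry",
                      fit_lv_ellipsoid((mask == 1 | mask == 2) * 1, vs))
  }
  say("  Ra %.1f µm, Rb %.1f µm, f %.1f µm", geometry$Ra, geometry$Rb,
      geometry$f)
  say("helical/intrusion angles (%s)", config$angle_method)
  angles <- stage("angles",
                  compute_angles(orient, geometry, mask,
                                 method = config$angle_method))
  say("disarray index (window %d = %.0f µm)", config$mdi_window,
      config$mdi_window * mean(vs))
  mdi <- stage("mdi", compute_mdi(orient, mask, window = config$mdi_window))
  say("transmural depth")
  depth <- stage("depth",
                 transmural_depth(mask, geometry, vs,
                                  septum_reverse = config$septum_reverse))
  say("sectors, levels, AHA segments")
  sectors <- stage("sectors",
                   define_walls_and_levels(mask, geometry, vs, anchor,
                                           config$level_fracs,
                                           config$slab_slices))
  aha <- stage("aha", aha_segmentation(mask, geometry, vs, anchor))
  say("classifications + region summaries")
  wall_regions <- array(NA_integer_, dim(mask))
  wall_regions[mask != 0] <- mask[mask != 0]
  region_summary <- stage("summaries", summarize_regions(
    wall_regions, fa, mdi, angles,
    region_names = c("1" = "LV free wall", "2" = "septum",
                     "3" = "RV free wall")
  ))
  aha_summary <- stage("summaries", summarize_regions(
    aha, fa, mdi, angles, region_names = aha_segment_names()
  ))
  classifications <- stage("classify", classify_angles(
    angles, mask, ha_threshold = config$ha_threshold,
    ia_thresholds = config$ia_thresholds
  ))
  say("transmural profile fits")
  fits <- stage("profiles",
                fit_transmural_profile(depth, angles, sectors,
                                       config$min_profile_voxels))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(
    list(volume = volume, mask = mask, orientation = orient, fa = fa,
         mdi = mdi, angles = angles, depth = depth, geometry = geometry,
         sectors = sectors, aha = aha, fits = fits,
         region_summary = region_summary, aha_summary = aha_summary,
         classifications = classifications, config = config),
    class = "pipeline_result"
  )
}

#' Write a pipeline report bundle to disk
#'
#' Emits the NRRD maps (FA, MDI, HA, IA, depth, AHA labels, v3), the CSV
#' tables (region summary, AHA summary, profile fits, classifications), a
#' glyph export of the mid z-slice, and a YAML snapshot of the configuration
#' so every number is traceable to its parameters.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed); defaults to
#'   `result$config$output_dir`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  dir <- dir %||% result$config$output_dir
  if (is.null(dir)) stop("no output directory configured", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- result$volume$voxel_size_um
  wn <- function(a, f, type = "float") {
    write_nrrd(a, file.path(dir, f), spacing = vs, type = type)
  }
  wn(result$fa$fa, "fa.nrrd")
  wn(result$mdi$mdi, "mdi.nrrd")
  wn(result$angles$ha, "ha_deg.nrrd")
  wn(result$angles$ia, "ia_deg.nrrd")
  wn(result$depth$depth, "depth.nrrd")
  aha <- result$aha
  aha[is.na(aha)] <- -1L
  wn(aha, "aha_labels.nrrd", type = "int16")
  wn(aperm(result$orientation$v3, c(4, 1, 2, 3)), "v3.nrrd") # component-first
  wcsv <- function(df, f) {
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  }
  wcsv(result$region_summary, "region_summary.csv")
  wcsv(result$aha_summary, "aha_summary.csv")
  wcsv(tidy(result$fits), "profile_fits.csv")
  wcsv(result$classifications, "classifications.csv")
  slices <- result$config$glyph_slices %||% (dim(result$mask)[3] %/% 2)
  try(export_glyphs(result$orientation, result$angles, result$mask, slices,
                    file.path(dir, "glyphs_midslice.vtk")), silent = TRUE)
  save_config(result$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
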