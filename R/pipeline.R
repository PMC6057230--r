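## ---- end-to-end studies ------------------------------------------------
## These bind simulator -> reconstruction -> quantification at the
## "desk" problem sizes documented in the methods vignette: a reduced
## spectral sampling (256 samples over 470--640 nm, giving ~0.9 um axial
## sampling and ~83 um depth range in tissue) and 5 um lateral pitch for
## en-face counting, 2.5 um for 3-D morphometry. Plaque statistics,
## optical contrasts and analysis windows are the study conditions and do
## not change with these sizes.

derive_seed <- function(seed, salt) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(salt)
}

#' Simulate and analyze a large-field en-face mosaic
#'
#' Full areal plaque-load study: a square phantom is generated from the
#' fixture, every mosaic tile is acquired as a raw spectral volume and
#' reconstructed, the first `enface_thickness` um under the detected
#' surface are projected, the tiles are stitched, plaques are segmented
#' in the mosaic and the areal plaque load is computed.
#'
#' @param fixture fixture name or [fixture()] object.
#' @param seed integer seed (phantom and detector noise).
#' @param side_mm,tile_mm,overlap_fraction mosaic geometry
#'   (see [plan_mosaic()]).
#' @param a_scans_per_tile tile raster (per side).
#' @param samples,wavelength_range spectral sampling of the simulated
#'   acquisition.
#' @param slab phantom slab thickness, um.
#' @param voxel phantom voxel spacing, um.
#' @param dispersion forward/compensated dispersion coefficients.
#' @param window apodization window.
#' @param enface_offset,enface_thickness projection window below the
#'   surface, um.
#' @param threshold_sigmas,size_range,pre_smooth segmentation parameters
#'   (no pre-smoothing by default: at 5 um pitch a box filter would push
#'   the smallest plaques below threshold).
#' @param constants an [optical_constants()].
#' @param refine refine tile placement by registration while stitching.
#' @return A list: `load` (plaques/mm2), `truth_load`, `table`
#'   (segmented `plaque_table`), `truth` (phantom plaque truth), `mosaic`
#'   (stitched matrix), `pixel_um`, `plan`, `seed`.
#' @export
run_mosaic_study <- function(fixture, seed, side_mm = 2.5, tile_mm = 0.5,
                             overlap_fraction = 1 / 3,
                             a_scans_per_tile = 100, samples = 256,
                             wavelength_range = c(470, 640), slab = 72,
                             voxel = c(5, 5, 2.5), dispersion = c(3, 0.5),
                             window = "hann", enface_offset = 0,
                             enface_thickness = 50, threshold_sigmas = 3,
                             size_range = c(10, 70), pre_smooth = 0,
                             constants = optical_constants(),
                             refine = TRUE) {
  fx <- if (inherits(fixture, "ocm_fixture")) fixture else
    fixture(fixture)
  plan <- plan_mosaic(side_mm, tile_mm, overlap_fraction)
  ph <- build_phantom(fx, seed, extent = rep(side_mm * 1000, 2),
                      slab = slab, voxel = voxel)
  sp <- source_spectrum(wavelength_range = wavelength_range,
                        samples = samples)
  nt <- nrow(plan$tile_origins)
  tiles <- vector("list", nt)
  for (t in seq_len(nt)) {
    sc <- scan_config(samples_per_spectrum = samples,
                      a_scans = a_scans_per_tile,
                      b_scans = a_scans_per_tile,
                      lateral_fov = tile_mm * 1000, slab_thickness = slab,
                      dispersion_coefficients = dispersion,
                      noise_seed = derive_seed(seed, t))
    raw <- simulate_raw_volume(ph, sp, constants, sc,
                               origin = c(plan$tile_origins$x_um[t],
                                          plan$tile_origins$y_um[t]))
    vol <- ocm_reconstruct(raw, window = window, dispersion = dispersion)
    surf <- detect_surface(vol)
    tiles[[t]] <- enface_projection(vol, surf, enface_offset,
                                    enface_thickness)
  }
  st <- stitch_tiles(tiles, plan, refine = refine)
  seg <- segment_plaques(st$mosaic, threshold_sigmas = threshold_sigmas,
                         size_range = size_range, pre_smooth = pre_smooth,
                         spacing = rep(st$pixel_um, 2))
  area_mm2 <- side_mm^2
  list(load = plaque_load(seg$table, area_mm2),
       truth_load = nrow(ph$plaque_truth) / area_mm2,
       table = seg$table, truth = ph$plaque_truth, labels = seg$labels,
       mosaic = st$mosaic, pixel_um = st$pixel_um, plan = plan,
       seed = seed)
}

#' Simulate and analyze a single 3-D volume
#'
#' Full volumetric morphometry study: a phantom is generated from a
#' (typically volumetric) fixture, one field of view is acquired and
#' reconstructed, plaques are segmented in 3-D, and per-plaque volumes,
#' the volumetric load and (optionally) CNR statistics on randomly
#' sampled plaques are reported.
#'
#' @inheritParams run_mosaic_study
#' @param extent_um lateral field of view, um.
#' @param lateral_um A-scan pitch, um.
#' @param cnr_n number of plaques to sample for CNR (0 = skip).
#' @return A list: `table` (3-D `plaque_table`), `mean_volume_um3`,
#'   `load_mm3` (plaques/mm3), `truth`, `truth_mean_volume_um3`, `rois`
#'   (CNR table or NULL), `seg`, `seed`.
#' @export
run_volume_study <- function(fixture, seed, extent_um = 620, slab = 70,
                             voxel = c(2.5, 2.5, 1.25), lateral_um = 2.5,
                             samples = 256,
                             wavelength_range = c(470, 640),
                             dispersion = c(3, 0.5), window = "hann",
                             threshold_sigmas = 3, size_range = c(10, 70),
                             cnr_n = 0,
                             constants = optical_constants()) {
  fx <- if (inherits(fixture, "ocm_fixture")) fixture else
    fixture(fixture)
  ph <- build_phantom(fx, seed, extent = rep(extent_um, 2), slab = slab,
                      voxel = voxel)
  sp <- source_spectrum(wavelength_range = wavelength_range,
                        samples = samples)
  na <- round(extent_um / lateral_um)
  sc <- scan_config(samples_per_spectrum = samples, a_scans = na,
                    b_scans = na, lateral_fov = extent_um,
                    slab_thickness = slab,
                    dispersion_coefficients = dispersion,
                    noise_seed = derive_seed(seed, 1L))
  raw <- simulate_raw_volume(ph, sp, constants, sc)
  vol <- ocm_reconstruct(raw, window = window, dispersion = dispersion)
  rm(raw)
  seg <- segment_plaques(vol, threshold_sigmas = threshold_sigmas,
                         size_range = size_range)
  rois <- NULL
  if (cnr_n > 0) {
    n_use <- min(cnr_n, nrow(seg$table))
    if (n_use > 0)
      rois <- sample_plaque_rois(seg, n_use, seed = derive_seed(seed, 2L))
  }
  vol_mm3 <- (extent_um / 1000)^2 * slab / 1000
  list(table = seg$table,
       mean_volume_um3 = if (nrow(seg$table)) mean(seg$table$volume_um3)
       else NA_real_,
       load_mm3 = plaque_load(seg$table, vol_mm3),
       truth = ph$plaque_truth,
       truth_mean_volume_um3 = if (nrow(ph$plaque_truth))
         mean(ph$plaque_truth$volume_um3) else NA_real_,
       rois = rois, seg = seg, seed = seed)
}

#' Compare two study groups with KS tests
#'
#' Runs [ks_two_sample()] on one or more per-plaque quantities of two
#' `plaque_table`s (or ROI tables), Bonferroni-adjusting over the
#' declared comparison family.
#'
#' @param table_a,table_b data frames with the requested columns.
#' @param columns columns to compare.
#' @param comparisons_m Bonferroni family size (default: number of
#'   columns).
#' @param alpha significance level.
#' @return A list of `stat_report`s, one per column.
#' @export
compare_groups <- function(table_a, table_b,
                           columns = "eq_diameter_um",
                           comparisons_m = length(columns),
                           alpha = 0.05) {
  out <- lapply(columns, function(cl) {
    ks_two_sample(table_a[[cl]], table_b[[cl]], alpha = alpha,
                  comparisons_m = comparisons_m,
                  test_name = sprintf("two-sample KS on %s", cl))
  })
  names(out) <- columns
  out
}

#' Run the full pipeline from a configuration
#'
#' Orchestrates simulate -> reconstruct -> quantify -> stats for one
#' fixture and writes every stage product to the output directory:
#' the stitched mosaic or en-face image (float TIFF), the plaque table
#' (CSV + JSON summary), CNR ROI statistics (volume mode), the diameter
#' group summary (JSON) and a run manifest with configuration hash, seeds
#' and per-file MD5 checksums. Re-running an identical configuration
#' reproduces identical checksums.
#'
#' @param config a `pipeline_config` from [load_config()] /
#'   [default_config()].
#' @param quiet suppress stage messages.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  stage <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  t_all <- proc.time()[["elapsed"]]
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fx <- fixture(config$fixture)
  if (!is.null(config$phantom$density)) fx$density <- config$phantom$density
  cons <- do.call(optical_constants, config$constants)
  seed <- as.integer(config$seed)
  files <- character(0)
  qc <- config$quantification

  if (identical(config$mode, "mosaic")) {
    stage("[simulate+reconstruct] mosaic study, fixture '%s', seed %d",
          config$fixture, seed)
    res <- run_mosaic_study(
      fx, seed, side_mm = config$mosaic$side_mm,
      tile_mm = config$mosaic$tile_mm,
      overlap_fraction = config$mosaic$overlap_fraction,
      a_scans_per_tile = config$scan$a_scans,
      samples = config$scan$samples_per_spectrum,
      wavelength_range = config$spectrum$wavelength_range,
      slab = config$scan$slab_thickness,
      voxel = config$phantom$voxel,
      dispersion = config$scan$dispersion_coefficients,
      window = config$reconstruction$window,
      enface_offset = config$reconstruction$enface_offset,
      enface_thickness = config$reconstruction$enface_thickness,
      threshold_sigmas = qc$threshold_sigmas,
      size_range = qc$size_range, constants = cons)
    stage("[quantify] %d plaques, %.2f plaques/mm2", nrow(res$table),
          res$load)
    files <- c(files,
      save_enface(structure(list(values = res$mosaic,
                                 pixel_spacing = rep(res$pixel_um, 2),
                                 window_offset =
                                   config$reconstruction$enface_offset,
                                 window_thickness =
                                   config$reconstruction$enface_thickness,
                                 projection_mode = "mean-linear"),
                            class = "enface_image"),
                  file.path(out, "mosaic.tif")),
      write_plaque_table(res$table, file.path(out, "plaques.csv"),
                         extent = config$mosaic$side_mm^2))
    values <- res$table$eq_diameter_um
    extent_label <- "plaques/mm2"
    load_val <- res$load
  } else {
    stage("[simulate+reconstruct] volume study, fixture '%s', seed %d",
          config$fixture, seed)
    res <- run_volume_study(
      fx, seed, extent_um = config$scan$lateral_fov,
      slab = config$scan$slab_thickness, voxel = config$phantom$voxel,
      lateral_um = config$scan$lateral_fov / config$scan$a_scans,
      samples = config$scan$samples_per_spectrum,
      wavelength_range = config$spectrum$wavelength_range,
      dispersion = config$scan$dispersion_coefficients,
      window = config$reconstruction$window,
      threshold_sigmas = qc$threshold_sigmas,
      size_range = qc$size_range, cnr_n = qc$cnr_n, constants = cons)
    stage("[quantify] %d plaques, %.0f plaques/mm3", nrow(res$table),
          res$load_mm3)
    vol_mm3 <- (config$scan$lateral_fov / 1000)^2 *
      config$scan$slab_thickness / 1000
    files <- c(files,
      write_plaque_table(res$table, file.path(out, "plaques.csv"),
                         extent = vol_mm3))
    if (!is.null(res$rois)) {
      write.csv(res$rois, file.path(out, "cnr_rois.csv"),
                row.names = FALSE)
      files <- c(files, file.path(out, "cnr_rois.csv"))
    }
    values <- res$table$eq_diameter_um
    extent_label <- "plaques/mm3"
    load_val <- res$load_mm3
  }

  stage("[stats] group summary over %d plaques", length(values))
  gs <- summarize_group(values, label = config$fixture)
  jsonlite::write_json(unclass(gs), file.path(out, "group_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, file.path(out, "group_summary.json"))

  cfg_file <- file.path(out, "config.yaml")
  save_config(config, cfg_file)
  ## configuration hash over the scientific settings only (the output
  ## directory does not change the run)
  hash_cfg <- config
  hash_cfg$output_dir <- NULL
  tf <- tempfile(fileext = ".yaml")
  save_config(hash_cfg, tf)
  cfg_md5 <- unname(tools::md5sum(tf))
  unlink(tf)
  checks <- as.list(tools::md5sum(c(files, paste0(
    files[grepl("[.]tif$|[.]csv$", files)], ".json"))))
  names(checks) <- basename(names(checks))
  manifest <- list(
    package_version = as.character(utils::packageVersion("visocm")),
    fixture = config$fixture, mode = config$mode, seed = seed,
    config_md5 = cfg_md5,
    load = load_val, load_units = extent_label,
    n_plaques = length(values),
    checksums = checks,
    elapsed_s = round(proc.time()[["elapsed"]] - t_all, 2))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage("[done] %s (%.1f s)", out, manifest$elapsed_s)
  invisible(manifest)
}
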