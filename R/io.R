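## ---- persistence -------------------------------------------------------
## Volumetric data go to multi-page 32-bit float TIFF with a JSON sidecar
## carrying spacings, seeds and provenance; tables go to CSV with a JSON
## summary. All formats are plain and re-readable by the module that
## wrote them.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a numeric volume as multi-page float TIFF
#'
#' Pages run along the first array dimension (depth for reconstructed
#' volumes). Values are stored as 32-bit floats scaled by `scale` (stored
#' in the sidecar so reading restores the original values).
#'
#' @param x 2-D or 3-D numeric array.
#' @param path output `.tif` path; a `<path>.json` sidecar holds
#'   metadata.
#' @param spacing per-dimension spacing in um.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(x, path, spacing = NULL, meta = list()) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% 2:3)
    stop("'x' must be a 2-D or 3-D numeric array", call. = FALSE)
  ## affine-map values into [0, 1]: float TIFF storage outside that range
  ## is undefined in libtiff-based writers
  lo <- min(x); hi <- max(x)
  scale <- if (hi > lo) hi - lo else 1
  xn <- (x - lo) / scale
  pages <- if (length(d) == 2L) list(xn) else
    lapply(seq_len(d[1]), function(i) matrix(xn[i, , ], d[2], d[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    c(list(dim = d, scale = scale, offset = lo, spacing_um = spacing),
      meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#'
#' @param path `.tif` path with its sidecar.
#' @return the numeric array, with attribute `meta` (sidecar contents).
#' @export
read_volume_tiff <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  off <- meta$offset %||% 0
  x <- if (length(d) == 2L) pages[[1]] * meta$scale + off else {
    a <- array(0, dim = d)
    for (i in seq_len(d[1])) a[i, , ] <- pages[[i]] * meta$scale + off
    a
  }
  attr(x, "meta") <- meta
  x
}

#' Write a plaque table as CSV with a JSON summary
#'
#' The CSV holds the per-plaque rows; the JSON summary records the count,
#' the load (when an extent is given) and mean/SD of volume and diameter.
#'
#' @param table a `plaque_table`.
#' @param path output `.csv` path.
#' @param extent optional area (mm2) or volume (mm3) for the load.
#' @return `path`, invisibly.
#' @export
write_plaque_table <- function(table, path, extent = NULL) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  summ <- list(
    count = nrow(table),
    load = if (!is.null(extent)) nrow(table) / extent else NULL,
    extent = extent,
    mean_diameter_um = mean(table$eq_diameter_um),
    sd_diameter_um = if (nrow(table) > 1) sd(table$eq_diameter_um) else NA,
    mean_volume_um3 = mean(table$volume_um3),
    sd_volume_um3 = if (nrow(table) > 1) sd(table$volume_um3) else NA)
  jsonlite::write_json(summ, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a plaque table CSV
#'
#' @param path `.csv` path.
#' @return a `plaque_table` data frame.
#' @export
read_plaque_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("plaque_table", "data.frame"))
}

#' Serialize a statistics report to JSON
#'
#' @param reports a `stat_report` or list of them.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_stat_reports <- function(reports, path) {
  if (inherits(reports, "stat_report")) reports <- list(reports)
  jsonlite::write_json(lapply(reports, unclass), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Persist a raw spectral volume
#'
#' Spectra go to multi-page float TIFF (pages along the spectral axis);
#' the sidecar stores the wavelength axis and the acquisition parameters,
#' so [read_raw_volume()] restores a working `raw_spectral_volume`.
#'
#' @param raw a [simulate_raw_volume()] result.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_raw_volume <- function(raw, path) {
  write_volume_tiff(raw$spectra, path,
    meta = list(kind = "raw_spectral_volume",
                wavelength_axis = raw$wavelength_axis,
                reference_spectrum = raw$reference_spectrum,
                scan = unclass(raw$scan),
                source = list(center_wavelength = raw$source$center_wavelength,
                              fwhm_bandwidth = raw$source$fwhm_bandwidth),
                constants = unclass(raw$constants),
                origin = raw$origin))
  invisible(path)
}

#' Restore a raw spectral volume saved by [save_raw_volume()]
#'
#' @param path `.tif` path.
#' @return a `raw_spectral_volume`.
#' @export
read_raw_volume <- function(path) {
  x <- read_volume_tiff(path)
  meta <- attr(x, "meta")
  if (!identical(meta$kind, "raw_spectral_volume"))
    stop("not a saved raw_spectral_volume", call. = FALSE)
  attr(x, "meta") <- NULL
  sc <- meta$scan
  structure(list(
    spectra = x,
    wavelength_axis = as.numeric(meta$wavelength_axis),
    scan = scan_config(sc$samples_per_spectrum, sc$a_scans, sc$b_scans,
                       sc$lateral_fov, sc$slab_thickness,
                       as.numeric(sc$dispersion_coefficients),
                       sc$noise_seed),
    source = list(center_wavelength = meta$source$center_wavelength,
                  fwhm_bandwidth = meta$source$fwhm_bandwidth),
    constants = do.call(optical_constants, meta$constants),
    origin = as.numeric(meta$origin),
    reference_spectrum = as.numeric(meta$reference_spectrum)),
    class = "raw_spectral_volume")
}

#' Persist an en-face image
#'
#' @param image an `enface_image` (or numeric matrix).
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
save_enface <- function(image, path) {
  if (inherits(image, "enface_image")) {
    write_volume_tiff(image$values, path,
                      spacing = image$pixel_spacing,
                      meta = list(kind = "enface_image",
                                  window_offset = image$window_offset,
                                  window_thickness = image$window_thickness,
                                  projection_mode = image$projection_mode))
  } else {
    write_volume_tiff(image, path, meta = list(kind = "enface_image"))
  }
  invisible(path)
}

#' Read an en-face image saved by [save_enface()]
#'
#' @param path `.tif` path.
#' @return an `enface_image`.
#' @export
read_enface <- function(path) {
  x <- read_volume_tiff(path)
  meta <- attr(x, "meta")
  attr(x, "meta") <- NULL
  structure(list(values = x,
                 pixel_spacing = as.numeric(meta$spacing_um %||% c(1, 1)),
                 window_offset = meta$window_offset %||% 0,
                 window_thickness = meta$window_thickness %||% NA,
                 projection_mode = meta$projection_mode %||% "mean-linear"),
            class = "enface_image")
}
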