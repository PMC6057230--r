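## ---- pipeline configuration -------------------------------------------

#' Default pipeline configuration
#'
#' The full configuration tree with the standard protocol defaults:
#' 8192 x 500 x 500 acquisition raster, Hann window, 0--50 um en-face
#' window, a 10--70 um equivalent-diameter gate, 25 CNR plaques and a
#' 0.05 significance level. Any subset of fields can be overridden from a
#' YAML/JSON file via [load_config()].
#'
#' @return A `pipeline_config` (nested named list).
#' @export
default_config <- function() {
  structure(list(
    fixture = "aged_mouse",
    seed = 1L,
    mode = "volume",                    # "volume" or "mosaic"
    scan = list(
      samples_per_spectrum = 8192L,
      a_scans = 500L,
      b_scans = 500L,
      lateral_fov = 500,
      slab_thickness = 200,
      dispersion_coefficients = c(3, 0.5)),
    spectrum = list(
      center_wavelength = 555,
      fwhm_bandwidth = 156,
      wavelength_range = c(425, 680)),
    constants = list(
      group_index_tissue = 1.36,
      sensitivity_db = 91,
      rolloff_db_per_mm = 24,
      clearing_depth_factor = 2),
    phantom = list(
      voxel = c(2.5, 2.5, 1.25),
      density = NULL),                  # NULL: fixture default
    mosaic = list(
      side_mm = 2.5,
      tile_mm = 0.5,
      overlap_fraction = 1 / 3),
    reconstruction = list(
      window = "hann",
      enface_offset = 0,
      enface_thickness = 50,
      attenuation = FALSE),
    quantification = list(
      threshold_sigmas = 3,
      size_range = c(10, 70),
      cnr_n = 25L),
    statistics = list(
      family_size = 1L,
      alpha = 0.05),
    output_dir = "visocm-out"),
    class = "pipeline_config")
}

validate_config <- function(cfg, ref = default_config(), path = "") {
  for (nm in names(cfg)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(ref))
      stop(sprintf("unknown configuration field '%s'", here), call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(cfg[[nm]])) {
      if (!is.list(cfg[[nm]]))
        stop(sprintf("field '%s' must be a mapping", here), call. = FALSE)
      validate_config(cfg[[nm]], ref[[nm]], here)
    }
  }
  dens <- cfg$phantom$density
  if (!is.null(dens) && (!is.numeric(dens) || dens < 0))
    stop("field 'phantom.density' must be a non-negative number",
         call. = FALSE)
  for (f in c("scan.samples_per_spectrum", "scan.a_scans", "scan.b_scans")) {
    parts <- strsplit(f, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!is.null(v) && (!is.numeric(v) || v < 1))
      stop(sprintf("field '%s' must be a positive count", f), call. = FALSE)
  }
  al <- cfg$statistics$alpha
  if (!is.null(al) && (al <= 0 || al >= 1))
    stop("field 'statistics.alpha' must lie in (0, 1)", call. = FALSE)
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_config(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON, a YAML subset) file, validates it against the
#' configuration schema (unknown keys are rejected with their path) and
#' merges it over [default_config()]. An empty file yields the defaults.
#'
#' @param path configuration file path.
#' @param ... named overrides applied after the file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop(sprintf("configuration file '%s' does not exist", path),
           call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user))
        stop("configuration file must contain a mapping", call. = FALSE)
      validate_config(user)
      cfg <- merge_config(cfg, user)
    }
  }
  dots <- list(...)
  if (length(dots)) {
    validate_config(dots)
    cfg <- merge_config(cfg, dots)
  }
  validate_config(unclass(cfg))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "pipeline_config: fixture '%s', %s mode, seed %d -> '%s'\n",
    x$fixture, x$mode, as.integer(x$seed), x$output_dir))
  invisible(x)
}
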