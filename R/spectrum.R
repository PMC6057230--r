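#' Broadband source spectrum
#'
#' Describes the power spectral envelope of the supercontinuum-derived
#' visible source used for spectral-domain OCM. The default is a Gaussian
#' envelope centred at 555 nm with 156 nm full width at half maximum,
#' sampled on 425--680 nm. The envelope may be sampled uniformly in
#' wavelength (as a grating spectrometer does) or uniformly in wavenumber
#' (handy for analytic checks, since no k-resampling is then needed).
#'
#' @param center_wavelength centre wavelength lambda0 in nm.
#' @param fwhm_bandwidth full width at half maximum of the envelope in nm.
#' @param wavelength_range length-2 numeric, sampled wavelength span in nm.
#' @param samples number of spectral samples.
#' @param sampling `"wavelength"` for a uniform-lambda axis, `"wavenumber"`
#'   for a uniform-k axis.
#' @param shape `"gaussian"` or `"flat"` (unit envelope, used for
#'   windowing-theory checks).
#' @return An object of class `source_spectrum` with fields
#'   `center_wavelength`, `fwhm_bandwidth`, `wavelength_axis` (nm, strictly
#'   increasing) and `envelope` (non-negative).
#' @examples
#' sp <- source_spectrum(samples = 2048)
#' spectrum_fwhm(sp)  # close to 156 nm
#' @export
source_spectrum <- function(center_wavelength = 555, fwhm_bandwidth = 156,
                            wavelength_range = c(425, 680), samples = 8192,
                            sampling = c("wavelength", "wavenumber"),
                            shape = c("gaussian", "flat")) {
  sampling <- match.arg(sampling)
  shape <- match.arg(shape)
  stopifnot_scalar_num(center_wavelength, "center_wavelength", lower = 1)
  stopifnot_scalar_num(fwhm_bandwidth, "fwhm_bandwidth", lower = 1e-6)
  stopifnot_scalar_num(samples, "samples", lower = 8)
  if (length(wavelength_range) != 2L || diff(wavelength_range) <= 0)
    stop("'wavelength_range' must be an increasing length-2 vector (nm)",
         call. = FALSE)
  if (sampling == "wavelength") {
    lambda <- seq(wavelength_range[1], wavelength_range[2],
                  length.out = samples)
  } else {
    k <- seq(2 * pi / wavelength_range[2], 2 * pi / wavelength_range[1],
             length.out = samples)
    lambda <- rev(2 * pi / k)  # increasing in lambda, uniform in k
  }
  env <- switch(shape,
    gaussian = exp(-4 * log(2) * ((lambda - center_wavelength) /
                                    fwhm_bandwidth)^2),
    flat = rep(1, samples))
  structure(list(center_wavelength = center_wavelength,
                 fwhm_bandwidth = fwhm_bandwidth,
                 wavelength_axis = lambda,
                 envelope = env,
                 sampling = sampling,
                 shape = shape),
            class = "source_spectrum")
}

#' Measured FWHM of a source envelope
#'
#' Full width at half maximum of the sampled envelope by linear
#' interpolation, in nm. For a Gaussian envelope this agrees with the
#' nominal `fwhm_bandwidth` to within one wavelength sample.
#'
#' @param spectrum a [source_spectrum()].
#' @return FWHM in nm.
#' @export
spectrum_fwhm <- function(spectrum) {
  fwhm_interp(spectrum$envelope, spectrum$wavelength_axis)
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf(
    "source_spectrum: lambda0 = %g nm, FWHM = %g nm, %d samples (%s, %s)\n",
    x$center_wavelength, x$fwhm_bandwidth, length(x$wavelength_axis),
    x$sampling, x$shape))
  invisible(x)
}

#' Optical constants of the OCM system and tissue
#'
#' System-level scalars: the tissue group refractive index used to convert
#' optical depth to geometric depth, the shot-noise-limited sensitivity in
#' dB (signal-to-noise of a unit reflector at zero depth), the spectrometer
#' sensitivity roll-off in dB per mm of depth, and the factor by which
#' optical clearing extends the penetration depth (applied as a divisor on
#' tissue attenuation).
#'
#' @param group_index_tissue dimensionless group refractive index, >= 1.
#' @param sensitivity_db sensitivity in dB.
#' @param rolloff_db_per_mm sensitivity roll-off in dB/mm (>= 0).
#' @param clearing_depth_factor >= 1; 1 means uncleared tissue.
#' @return An object of class `optical_constants`.
#' @export
optical_constants <- function(group_index_tissue = 1.36, sensitivity_db = 91,
                              rolloff_db_per_mm = 24,
                              clearing_depth_factor = 2) {
  stopifnot_scalar_num(group_index_tissue, "group_index_tissue", lower = 1)
  stopifnot_scalar_num(sensitivity_db, "sensitivity_db")
  stopifnot_scalar_num(rolloff_db_per_mm, "rolloff_db_per_mm", lower = 0)
  stopifnot_scalar_num(clearing_depth_factor, "clearing_depth_factor",
                       lower = 1)
  structure(list(group_index_tissue = group_index_tissue,
                 sensitivity_db = sensitivity_db,
                 rolloff_db_per_mm = rolloff_db_per_mm,
                 clearing_depth_factor = clearing_depth_factor),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf(paste0(
    "optical_constants: n_g = %g, sensitivity = %g dB, ",
    "roll-off = %g dB/mm, clearing factor = %g\n"),
    x$group_index_tissue, x$sensitivity_db, x$rolloff_db_per_mm,
    x$clearing_depth_factor))
  invisible(x)
}

#' Acquisition geometry of one OCM volume
#'
#' @param samples_per_spectrum spectral samples per A-scan.
#' @param a_scans,b_scans lateral raster size.
#' @param lateral_fov lateral field of view in um (square field).
#' @param slab_thickness tissue slab thickness in um.
#' @param dispersion_coefficients numeric vector `c(c2, c3)` of quadratic
#'   and cubic phase coefficients about the centre wavenumber, in um^2 and
#'   um^3 (phase in radians for k in 1/um).
#' @param noise_seed integer seed for the detector noise stream (NULL means
#'   take whatever the current RNG state gives).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(samples_per_spectrum = 8192, a_scans = 500,
                        b_scans = 500, lateral_fov = 500,
                        slab_thickness = 200,
                        dispersion_coefficients = c(0, 0),
                        noise_seed = NULL) {
  stopifnot_scalar_num(samples_per_spectrum, "samples_per_spectrum", lower = 8)
  stopifnot_scalar_num(a_scans, "a_scans", lower = 1)
  stopifnot_scalar_num(b_scans, "b_scans", lower = 1)
  stopifnot_scalar_num(lateral_fov, "lateral_fov", lower = 1e-6)
  stopifnot_scalar_num(slab_thickness, "slab_thickness", lower = 1e-6)
  if (!is.numeric(dispersion_coefficients) ||
      length(dispersion_coefficients) > 2L ||
      any(!is.finite(dispersion_coefficients)))
    stop("'dispersion_coefficients' must be finite c(c2, c3)", call. = FALSE)
  dispersion_coefficients <- c(dispersion_coefficients,
                               rep(0, 2 - length(dispersion_coefficients)))
  structure(list(samples_per_spectrum = as.integer(samples_per_spectrum),
                 a_scans = as.integer(a_scans),
                 b_scans = as.integer(b_scans),
                 lateral_fov = lateral_fov,
                 slab_thickness = slab_thickness,
                 dispersion_coefficients = dispersion_coefficients,
                 noise_seed = noise_seed),
            class = "scan_config")
}

#' Theoretical axial resolution (coherence length)
#'
#' The round-trip coherence length of a Gaussian source,
#' `(2 ln 2 / pi) * lambda0^2 / dlambda`, i.e. the FWHM of the amplitude
#' point spread function in the medium of propagation. With the default
#' 555 nm / 156 nm source this is 0.871 um in air.
#'
#' @param center_wavelength lambda0 in nm.
#' @param fwhm_bandwidth dlambda in nm.
#' @return axial resolution in um.
#' @export
coherence_length <- function(center_wavelength = 555, fwhm_bandwidth = 156) {
  (2 * log(2) / pi) * center_wavelength^2 / fwhm_bandwidth / 1000
}

#' Convert an axial resolution measured in air to tissue
#'
#' Depth in tissue is optical depth divided by the group refractive index,
#' so an axial resolution of 1.2 um measured on a mirror in air corresponds
#' to 1.2 / 1.36 = 0.88 um in brain tissue.
#'
#' @param resolution_air resolution in um measured in air.
#' @param group_index tissue group refractive index.
#' @param digits rounding applied to the reported value (default 2, the
#'   precision customary for this figure); use `NULL` for no rounding.
#' @return resolution in um in tissue.
#' @export
axial_resolution_tissue <- function(resolution_air, group_index = 1.36,
                                    digits = 2) {
  stopifnot_scalar_num(resolution_air, "resolution_air", lower = 0)
  stopifnot_scalar_num(group_index, "group_index", lower = 1)
  out <- resolution_air / group_index
  if (!is.null(digits)) out <- round(out, digits)
  out
}
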