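test_that("k-resampling passes k-uniform data through unchanged", {
  sp <- source_spectrum(samples = 512, sampling = "wavenumber")
  ph <- mirror_phantom(100.625)
  sc <- scan_config(samples_per_spectrum = 512, a_scans = 2, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  kv <- resample_to_k(raw)
  expect_lt(max(abs(kv$spectra - raw$spectra[rev(seq_len(512)), , ,
                                             drop = FALSE])) /
              max(abs(raw$spectra)), 1e-9)
})

test_that("a wavelength-uniform fringe reconstructs at its depth after resampling", {
  sp <- source_spectrum(samples = 2048)          # uniform in wavelength
  ph <- mirror_phantom(100.625)
  sc <- scan_config(samples_per_spectrum = 2048, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  vol <- ocm_reconstruct(raw, window = "hann", dispersion = c(0, 0))
  al <- Mod(vol$amplitude[, 1, 1])
  z_pk <- (which.max(al) - 1) * vol$axial_spacing_tissue
  expect_lt(abs(z_pk - 100.625), vol$axial_spacing_tissue)
})

test_that("skipping k-resampling broadens deep peaks substantially", {
  ## chirped lambda-uniform fringe from a deep reflector: transforming
  ## without resampling broadens the peak; resampling sharpens it by
  ## well over 1.5x
  sp <- source_spectrum(samples = 4096)
  ph <- mirror_phantom(1000.625, slab = 1100)
  sc <- scan_config(samples_per_spectrum = 4096, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 1100)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  vol <- ocm_reconstruct(raw, window = "hann", dispersion = c(0, 0),
                         pad_factor = 2)
  ## robust width: energy-equivalent width (total energy over peak power)
  ## near the reflector -- matches the FWHM scale for a clean peak and
  ## grows with any smearing, spiky or smooth
  width_eq <- function(vol) {
    prof <- Mod(vol$amplitude[, 1, 1])
    z <- (seq_along(prof) - 1) * vol$axial_spacing_air
    p <- prof[z > 900 & z < 1100]
    sum(p^2) / max(p^2) * vol$axial_spacing_air
  }
  w_res <- width_eq(vol)
  ## bypass resampling: pretend the lambda grid were already k-uniform
  raw2 <- raw
  k_f <- rev(2000 * pi / raw$wavelength_axis)
  fake_lambda <- rev(2000 * pi /
                       seq(k_f[1], k_f[length(k_f)], length.out = 4096))
  raw2$wavelength_axis <- fake_lambda
  raw2$reference_spectrum <- NULL
  vol2 <- ocm_reconstruct(raw2, window = "hann", dispersion = c(0, 0),
                          pad_factor = 2)
  w_chirp <- width_eq(vol2)
  expect_gt(w_chirp / w_res, 1.5)
})

test_that("dispersion compensation restores the dispersion-free PSF", {
  sp <- source_spectrum(samples = 2048)
  ph <- mirror_phantom(150.625)
  sc0 <- scan_config(samples_per_spectrum = 2048, a_scans = 1, b_scans = 1,
                     lateral_fov = 20, slab_thickness = 300)
  sc_d <- scan_config(samples_per_spectrum = 2048, a_scans = 1,
                      b_scans = 1, lateral_fov = 20, slab_thickness = 300,
                      dispersion_coefficients = c(3, 0.5))
  raw0 <- simulate_raw_volume(ph, sp, air_constants(), sc0, noise = FALSE)
  rawd <- simulate_raw_volume(ph, sp, air_constants(), sc_d, noise = FALSE)
  f0 <- measure_psf_fwhm(
    Mod(ocm_reconstruct(raw0, dispersion = c(0, 0),
                        pad_factor = 4)$amplitude[, 1, 1]), 1)
  fc <- measure_psf_fwhm(
    Mod(ocm_reconstruct(rawd, dispersion = c(3, 0.5),
                        pad_factor = 4)$amplitude[, 1, 1]), 1)
  pk_u <- max(Mod(ocm_reconstruct(rawd, dispersion = c(0, 0),
                                  pad_factor = 4)$amplitude[, 1, 1]))
  pk_c <- max(Mod(ocm_reconstruct(rawd, dispersion = c(3, 0.5),
                                  pad_factor = 4)$amplitude[, 1, 1]))
  pk_2 <- max(Mod(ocm_reconstruct(rawd, dispersion = c(6, 0.5),
                                  pad_factor = 4)$amplitude[, 1, 1]))
  expect_lt(abs(fc / f0 - 1), 0.05)   # compensated == dispersion-free
  expect_gt(pk_c / pk_u, 1.3)         # uncompensated energy is smeared
  expect_gt(pk_c, pk_2)               # over-compensation smears again
})

test_that("zero dispersion coefficients are an exact pass-through", {
  sp <- source_spectrum(samples = 256, sampling = "wavenumber")
  ph <- mirror_phantom(100.625)
  sc <- scan_config(samples_per_spectrum = 256, a_scans = 2, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  kv <- resample_to_k(raw)
  kv2 <- compensate_dispersion(kv, c(0, 0))
  expect_identical(Mod(kv2$spectra), abs(kv$spectra))
})

test_that("Hann shaping suppresses side lobes at a known cost in width", {
  ## flat envelope: classical window figures apply (first Hann side lobe
  ## -31.5 dB; main lobe 1.63x wider than rectangular)
  sp <- source_spectrum(samples = 1024, sampling = "wavenumber",
                        shape = "flat")
  ph <- mirror_phantom(150.625)
  sc <- scan_config(samples_per_spectrum = 1024, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE,
                             dc_level = 0)
  raw$reference_spectrum <- NULL
  vol_h <- ocm_reconstruct(raw, window = "hann", dispersion = c(0, 0),
                           pad_factor = 8)
  vol_r <- ocm_reconstruct(raw, window = "rectangular",
                           dispersion = c(0, 0), pad_factor = 8)
  first_sidelobe_db <- function(prof) {
    pk <- which.max(prof)
    right <- prof[pk:length(prof)]
    dips <- which(diff(sign(diff(right))) == 2) + 1
    lobe <- max(right[dips[1]:min(dips[1] + 200, length(right))])
    20 * log10(lobe / prof[pk])
  }
  ph_prof <- Mod(vol_h$amplitude[, 1, 1])
  pr_prof <- Mod(vol_r$amplitude[, 1, 1])
  expect_lt(first_sidelobe_db(ph_prof), -31)
  f_h <- measure_psf_fwhm(ph_prof, 1)
  f_r <- measure_psf_fwhm(pr_prof, 1)
  expect_gt(f_h / f_r, 1.4)
  expect_lt(f_h / f_r, 1.8)
})

test_that("with the shaped Gaussian spectrum side lobes drop >= 20 dB vs rectangular", {
  sp <- source_spectrum(samples = 1024, sampling = "wavenumber")
  ph <- mirror_phantom(150.625)
  sc <- scan_config(samples_per_spectrum = 1024, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE,
                             dc_level = 0)
  raw$reference_spectrum <- NULL
  lobe_level <- function(window) {
    vol <- ocm_reconstruct(raw, window = window, dispersion = c(0, 0),
                           pad_factor = 8)
    prof <- Mod(vol$amplitude[, 1, 1])
    pk <- which.max(prof)
    z <- abs(seq_along(prof) - pk) * vol$axial_spacing_air
    ## highest response 3-30 um away from the peak
    20 * log10(max(prof[z > 3 & z < 30]) / prof[pk])
  }
  expect_lt(lobe_level("hann") - lobe_level("rectangular"), -20)
})

test_that("an all-zero window is rejected and rectangular passes through", {
  sp <- source_spectrum(samples = 128, sampling = "wavenumber")
  ph <- mirror_phantom(50.625)
  sc <- scan_config(samples_per_spectrum = 128, a_scans = 2, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  kv <- resample_to_k(raw)
  expect_error(shape_spectrum(kv, rep(0, 128)), "all-zero")
  shaped <- shape_spectrum(kv, "rectangular")
  m <- matrix(kv$spectra, nrow = 128)
  centred <- m - rep(colMeans(m), each = 128)
  expect_equal(matrix(shaped$spectra, nrow = 128), centred,
               tolerance = 1e-12)
})

test_that("the axial PSF matches the coherence-length closed form", {
  ## 0.871 um in air for the 555/156 nm source; tissue value / 1.36
  ph <- mirror_phantom(100.625)
  sp <- source_spectrum(samples = 4096)
  sc <- scan_config(samples_per_spectrum = 4096, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  vol <- ocm_reconstruct(raw, window = "rectangular", dispersion = c(0, 0),
                         pad_factor = 8)
  prof <- Mod(vol$amplitude[, 1, 1])
  fwhm_air <- measure_psf_fwhm(prof, vol$axial_spacing_air)
  expect_lt(abs(fwhm_air / coherence_length() - 1), 0.10)
  ## expressed on a tissue-scaled depth axis the same peak reads
  ## fwhm_air / n_g
  oc <- optical_constants()
  fwhm_tissue <- measure_psf_fwhm(prof, vol$axial_spacing_air /
                                    oc$group_index_tissue)
  expect_equal(fwhm_tissue, fwhm_air / oc$group_index_tissue,
               tolerance = 1e-9)
})

test_that("measure_psf_fwhm recovers the width of a discrete Gaussian", {
  x <- seq(-40, 40, by = 0.5)
  y <- exp(-x^2 / (2 * 3^2))
  expect_lt(abs(measure_psf_fwhm(y, 0.5) / (2.3548 * 3) - 1), 0.02)
  expect_error(measure_psf_fwhm(c(5, 4, 3, 2, 1), 1), "boundary")
})

test_that("Parseval's identity links shaped spectrum and full A-line", {
  sp <- source_spectrum(samples = 512, sampling = "wavenumber")
  ph <- mirror_phantom(80.625)
  sc <- scan_config(samples_per_spectrum = 512, a_scans = 3, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300, noise_seed = 5)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc)
  kv <- compensate_dispersion(shape_spectrum(resample_to_k(raw), "hann"),
                              c(0, 0))
  vol <- reconstruct_volume(kv, keep = "full")
  e_spec <- sum(Mod(kv$spectra)^2)
  e_line <- sum(Mod(vol$amplitude)^2)
  expect_lt(abs(e_line / e_spec - 1), 1e-6)
})

test_that("the pipeline is linear in the input spectra", {
  ph <- slab_phantom(seed = 6, extent = c(100, 100), density = 40)
  acq <- acquire(ph, lateral_um = 5, noise = FALSE)
  raw2 <- acq$raw
  raw2$spectra <- raw2$spectra * 3.7
  raw2$reference_spectrum <- raw2$reference_spectrum * 3.7
  vol2 <- ocm_reconstruct(raw2, window = "hann", dispersion = c(0, 0))
  expect_equal(Mod(vol2$amplitude), 3.7 * Mod(acq$vol$amplitude),
               tolerance = 1e-9)
  ## dB image referenced to the floor is scale-invariant
  expect_equal(ocm_intensity_db(vol2), ocm_intensity_db(acq$vol),
               tolerance = 1e-6)
})
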