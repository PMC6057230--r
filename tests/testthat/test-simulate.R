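test_that("an isolated reflector reconstructs at its true depth", {
  ph <- mirror_phantom(100.625)
  sp <- source_spectrum(samples = 2048)
  sc <- scan_config(samples_per_spectrum = 2048, a_scans = 2, b_scans = 2,
                    lateral_fov = 20, slab_thickness = 300)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, noise = FALSE)
  vol <- ocm_reconstruct(raw, window = "rectangular", dispersion = c(0, 0))
  al <- Mod(vol$amplitude[, 1, 1])
  z_pk <- (which.max(al) - 1) * vol$axial_spacing_tissue
  expect_lt(abs(z_pk - 100.625), vol$axial_spacing_tissue)
})

test_that("a zero-backscatter phantom reconstructs to the noise floor", {
  ph <- mirror_phantom(100.625, R = 0)
  sp <- source_spectrum(samples = 512, sampling = "wavenumber")
  sc <- scan_config(samples_per_spectrum = 512, a_scans = 50, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 300, noise_seed = 3)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc)
  vol <- ocm_reconstruct(raw, window = "rectangular", dispersion = c(0, 0))
  I <- ocm_intensity(vol)
  ## away from the DC residual, everything sits at the noise floor
  deep <- I[-(1:20), , ]
  expect_lt(max(deep) / vol$noise_floor$median, 50)
  expect_lt(abs(median(deep) / vol$noise_floor$median - 1), 0.35)
})

test_that("sensitivity roll-off attenuates by its dB/mm rating", {
  ## reflectors 1 mm apart with equal reflectivity: amplitude ratio -24 dB
  ph <- mirror_phantom(c(200.625, 1200.625), slab = 1500)
  sp <- source_spectrum(samples = 8192)
  sc <- scan_config(samples_per_spectrum = 8192, a_scans = 1, b_scans = 1,
                    lateral_fov = 20, slab_thickness = 1500)
  raw <- simulate_raw_volume(ph, sp, air_constants(rolloff = 24), sc,
                             noise = FALSE)
  vol <- ocm_reconstruct(raw, window = "hann", dispersion = c(0, 0),
                         pad_factor = 2)
  al <- Mod(vol$amplitude[, 1, 1])
  z <- (seq_along(al) - 1) * vol$axial_spacing_tissue
  p1 <- max(al[z > 150 & z < 250])
  p2 <- max(al[z > 1150 & z < 1250])
  expect_lt(abs(20 * log10(p2 / p1) + 24), 1.5)
})

test_that("detector noise is calibrated to the stated sensitivity", {
  ## weak reflector (-60 dB) so side lobes stay below the noise floor;
  ## SNR averaged over 200 A-line noise realizations
  ph <- mirror_phantom(150.625, R = 1e-6)
  sp <- source_spectrum(samples = 1024, sampling = "wavenumber")
  sc <- scan_config(samples_per_spectrum = 1024, a_scans = 200,
                    b_scans = 1, lateral_fov = 20, slab_thickness = 300,
                    noise_seed = 7)
  raw <- simulate_raw_volume(ph, sp, air_constants(), sc, dc_level = 0)
  vol <- ocm_reconstruct(raw, window = "rectangular", dispersion = c(0, 0),
                         pad_factor = 4)
  I <- ocm_intensity(vol)
  z <- (seq_len(dim(I)[1]) - 1) * vol$axial_spacing_tissue
  peaks <- apply(I[z > 140 & z < 160, , 1], 2, max)
  noise <- I[z > 200 & z < 280, , 1]
  snr_db <- 10 * log10(mean(peaks) / mean(noise)) + 60
  expect_lt(abs(snr_db - 91), 1)
})

test_that("optical clearing doubles the depth at which signal is lost", {
  ## uniform attenuating phantom, roll-off disabled so Beer-Lambert decay
  ## dominates; the noise-floor crossing depth must double
  fx <- fixture("control", cells = FALSE, texture_sd = 1e-9,
                surface_height = 0, surface_ripple = 0,
                parenchyma_backscatter = 1e-4,
                parenchyma_attenuation = 40)
  ph <- build_phantom(fx, seed = 1, extent = c(40, 40), slab = 400,
                      voxel = c(10, 10, 0.625))
  sp <- source_spectrum(samples = 2048)
  sc <- scan_config(samples_per_spectrum = 2048, a_scans = 64, b_scans = 1,
                    lateral_fov = 40, slab_thickness = 400, noise_seed = 2)
  cross_depth <- function(clear) {
    oc <- optical_constants(group_index_tissue = 1.36,
                            rolloff_db_per_mm = 0,
                            clearing_depth_factor = clear)
    raw <- simulate_raw_volume(ph, sp, oc, sc)
    vol <- ocm_reconstruct(raw, window = "hann", dispersion = c(0, 0))
    prof <- runmed(apply(ocm_intensity(vol), 1, mean), 5)
    thr <- vol$noise_floor$median + 5 * vol$noise_floor$sigma
    ## solve the Beer-Lambert decay (linear in dB) for the threshold
    ## crossing, fitted where the signal is clearly above the floor
    z <- (seq_along(prof) - 1) * vol$axial_spacing_tissue
    db <- 10 * log10(prof)
    use <- prof > 20 * thr & z > 10
    fit <- lm(db[use] ~ z[use])
    (10 * log10(thr) - coef(fit)[1]) / coef(fit)[2]
  }
  d1 <- cross_depth(1)
  d2 <- cross_depth(2)
  expect_lt(abs(d2 - 2 * d1), 5)   # within a few axial pixels
})

test_that("simulation is deterministic under a fixed noise seed", {
  ph <- slab_phantom(seed = 2, extent = c(100, 100))
  sp <- source_spectrum(samples = 256, wavelength_range = c(470, 640))
  sc <- scan_config(samples_per_spectrum = 256, a_scans = 20, b_scans = 20,
                    lateral_fov = 100, slab_thickness = 72, noise_seed = 42)
  a <- simulate_raw_volume(ph, sp, optical_constants(), sc)
  b <- simulate_raw_volume(ph, sp, optical_constants(), sc)
  expect_identical(a$spectra, b$spectra)
})

test_that("axis mismatch and geometry violations are rejected", {
  ph <- slab_phantom(seed = 2, extent = c(100, 100))
  sp <- source_spectrum(samples = 128)
  sc <- scan_config(samples_per_spectrum = 256, a_scans = 10, b_scans = 10,
                    lateral_fov = 100, slab_thickness = 72)
  expect_error(simulate_raw_volume(ph, sp, optical_constants(), sc),
               "does not match")
  sp2 <- source_spectrum(samples = 256)
  sc2 <- scan_config(samples_per_spectrum = 256, a_scans = 10,
                     b_scans = 10, lateral_fov = 500)
  expect_error(simulate_raw_volume(ph, sp2, optical_constants(), sc2),
               "exceeds the phantom")
})
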