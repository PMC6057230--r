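test_that("truth masks reproduce the slice-intersection geometry", {
  ph <- grid_truth_phantom(diameters = c(30, 24, 36), z = 22)
  hs <- render_histology_stack(ph, seed = 41)
  ## geometry oracle: how many truth spheres cut at least one section
  cuts <- sapply(seq_len(nrow(ph$plaque_truth)), function(i)
    any(abs(hs$slice_z - ph$plaque_truth$z_um[i]) <
          ph$plaque_truth$diameter_um[i] / 2))
  expect_identical(sum(cuts), 12L)
  union <- Reduce(`|`, hs$masks)
  expect_identical(max(label_components(union)), 12L)
})

test_that("an empty phantom renders hematoxylin-only slides", {
  ph <- grid_truth_phantom()
  ph$plaque_truth <- ph$plaque_truth[0, ]
  hs <- render_histology_stack(ph, seed = 42)
  expect_true(all(sapply(hs$masks, sum) == 0))
  dab <- color_deconvolve(hs$slides[[1]], hs$stain_vectors)[, , "dab"]
  expect_lt(quantile(dab, 0.999), 0.2)
})

test_that("the default sectioning emulates every-third 3-um sections", {
  ph <- grid_truth_phantom()
  hs <- render_histology_stack(ph, seed = 43)
  expect_equal(diff(hs$slice_z), rep(9, 4))      # 3 um x (2 skipped + 1)
  expect_identical(length(hs$slides), 5L)
  expect_error(render_histology_stack(ph, n_slices = 0), "positive")
  expect_error(render_histology_stack(ph, n_slices = 8),
               "matched en-face window")
})

test_that("color deconvolution inverts the stain forward model", {
  M <- hdab_stain_vectors()
  ## pure white
  white <- array(1, dim = c(2, 2, 3))
  expect_equal(max(abs(color_deconvolve(white))), 0)
  ## DAB-only pixel at OD 0.8
  dab_rgb <- 10^(-0.8 * M["dab", ])
  img <- array(rep(dab_rgb, each = 4), dim = c(2, 2, 3))
  conc <- color_deconvolve(img)
  expect_lt(max(abs(conc[, , "dab"] - 0.8)), 1e-6)
  expect_lt(max(conc[, , "hematoxylin"]), 1e-6)
  ## hematoxylin-only pixel
  h_rgb <- 10^(-0.5 * M["hematoxylin", ])
  img2 <- array(rep(h_rgb, each = 4), dim = c(2, 2, 3))
  conc2 <- color_deconvolve(img2)
  expect_lt(max(conc2[, , "dab"]), 1e-6)
  ## collinear stain vectors are rejected
  expect_error(color_deconvolve(img, rbind(c(1, 0, 0), c(1, 0, 0))),
               "collinear")
})

test_that("translation registration recovers known shifts", {
  set.seed(44)
  ref <- box_smooth(matrix(rnorm(96 * 96), 96, 96), 2)
  expect_equal(unname(register_translation(ref, ref)), c(0, 0),
               tolerance = 1e-6)
  mov <- visocm:::shift_matrix(ref, 5, -3)
  sh <- register_translation(ref, mov)
  expect_lt(max(abs(sh - c(5, -3))), 0.5)
  expect_error(register_translation(ref, matrix(1, 96, 96)), "constant")
  ## robustness: 10% additive noise, >= 95% of trials within 1 px
  hits <- 0L
  for (i in 1:20) {
    dxy <- sample(-6:6, 2, replace = TRUE)
    noisy <- visocm:::shift_matrix(ref, dxy[1], dxy[2]) +
      matrix(rnorm(96 * 96, 0, 0.1 * diff(range(ref))), 96, 96)
    sh <- register_translation(ref, noisy, max_shift = 10)
    if (max(abs(sh - dxy)) <= 1) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("stack segmentation counts each plaque once across slides", {
  ph <- grid_truth_phantom(diameters = c(30, 24, 36), z = 22)
  hs <- render_histology_stack(ph, seed = 45)
  res <- segment_histology_stack(hs)
  expect_identical(nrow(res$table), 12L)
  expect_identical(res$table$source[1], "histology")
  ## a plaque cut by 3 of the 5 sections is still a single component:
  ## d = 20 at z = 20 spans 10-30 um, cutting sections 2-4 only
  ph2 <- grid_truth_phantom(diameters = 20, z = 20)
  hs2 <- render_histology_stack(ph2, seed = 46)
  cut_by <- sapply(hs2$slice_z, function(z)
    abs(z - 20) < 10)
  expect_identical(sum(cut_by), 3L)
  res2 <- segment_histology_stack(hs2)
  expect_identical(nrow(res2$table), 12L)
})

test_that("a blank stack segments to zero components", {
  ph <- grid_truth_phantom()
  ph$plaque_truth <- ph$plaque_truth[0, ]
  hs <- render_histology_stack(ph, seed = 47)
  res <- segment_histology_stack(hs, dab_threshold = 0.3)
  expect_identical(nrow(res$table), 0L)
})

test_that("OCM and histology counts agree on matched tissue", {
  ## same phantom, both counting routes; concordance within
  ## 3 sqrt(mean count)
  ph <- build_phantom("aged_mouse", seed = 48, extent = c(800, 800),
                      slab = 72, voxel = c(2.5, 2.5, 2.5))
  n_ocm <- nrow(segment_plaques(phantom_enface(ph, 0, 50),
                                pre_smooth = 0)$table)
  hq <- segment_histology_stack(render_histology_stack(ph, seed = 49))
  n_hist <- nrow(hq$table)
  m <- mean(c(n_ocm, n_hist))
  expect_gt(m, 5)
  expect_lt(abs(n_ocm - n_hist), 3 * sqrt(m))
})
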