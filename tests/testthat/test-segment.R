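test_that("a single bright blob is found and sized", {
  ## projected profile of a 30-um spherical deposit at 5-sigma contrast
  ## over noisy background
  set.seed(21)
  n <- 80; px <- 2.5
  xs <- (seq_len(n) - 0.5) * px
  img <- matrix(rnorm(n * n, 100, 2), n, n)
  rr <- sqrt(outer((xs - 100)^2, (xs - 100)^2, "+"))
  blob <- 10 * sqrt(pmax(1 - (rr / 15)^2, 0))
  seg <- segment_plaques(img + blob, spacing = c(px, px), pre_smooth = 1,
                         size_range = c(8, 100))
  expect_identical(nrow(seg$table), 1L)
  expect_lt(abs(seg$table$eq_diameter_um / 30 - 1), 0.2)
})

test_that("blank noise yields no components", {
  set.seed(22)
  img <- matrix(rnorm(100 * 100), 100, 100)
  seg <- segment_plaques(img, spacing = c(2, 2), size_range = c(6, 70))
  expect_identical(nrow(seg$table), 0L)
})

test_that("two separated blobs give two components at their centroids", {
  set.seed(23)
  n <- 100; px <- 2.5
  xs <- (seq_len(n) - 0.5) * px
  img <- matrix(rnorm(n * n, 10, 0.3), n, n)
  add_blob <- function(img, cx, cy)
    img + 3 * exp(-outer((xs - cx)^2, (xs - cy)^2, "+") / (2 * 8^2))
  img <- add_blob(add_blob(img, 75, 125), 175, 125)
  seg <- segment_plaques(img, spacing = c(px, px), pre_smooth = 1,
                         size_range = c(5, 100))
  expect_identical(nrow(seg$table), 2L)
  got <- sort(seg$table$x_um)
  expect_lt(max(abs(got - c(75, 175))), px)
  expect_lt(max(abs(seg$table$y_um - 125)), px)
})

test_that("a constant image warns and returns zero plaques", {
  img <- matrix(5, 50, 50)
  expect_warning(seg <- segment_plaques(img, spacing = c(2, 2)),
                 "constant image")
  expect_identical(nrow(seg$table), 0L)
})

test_that("morphometry follows the stated unit arithmetic", {
  lab <- matrix(0L, 11, 11); lab[6, 6] <- 1L
  tab <- plaque_morphometry(lab, c(2, 2))
  expect_equal(tab$area_um2, 4)
  expect_equal(tab$eq_diameter_um, 2 * sqrt(4 / pi), tolerance = 1e-9)
  expect_equal(tab$eq_diameter_um, 2.2568, tolerance = 1e-4)
  ## empty label map
  tab0 <- plaque_morphometry(matrix(0L, 5, 5), c(1, 1))
  expect_identical(nrow(tab0), 0L)
  ## voxelized sphere of radius 10 um at 1 um spacing
  d <- 25
  cc <- (d + 1) / 2
  dd <- sqrt(outer(outer((1:d - cc)^2, (1:d - cc)^2, "+"), (1:d - cc)^2,
                   "+"))
  arr <- array(0L, dim = c(d, d, d)); arr[dd <= 10] <- 1L
  tab3 <- plaque_morphometry(arr, c(1, 1, 1))
  expect_lt(abs(tab3$volume_um3 / (4 / 3 * pi * 1000) - 1), 0.10)
  expect_error(plaque_morphometry(lab, c(2, -2)), "positive")
})

test_that("plaque load is count per unit extent", {
  tab <- data.frame(id = 1:230)
  expect_equal(plaque_load(tab, 10), 23)
  expect_equal(plaque_load(tab[0, , drop = FALSE], 4), 0)
  expect_error(plaque_load(tab, 0), "extent")
  ## load times extent returns the count
  expect_equal(plaque_load(tab, 7.3) * 7.3, 230, tolerance = 1e-12)
})

test_that("raising the threshold never adds pixels or components", {
  set.seed(24)
  n <- 120; px <- 2.5
  xs <- (seq_len(n) - 0.5) * px
  img <- matrix(rnorm(n * n, 10, 0.4), n, n)
  centres <- cbind(c(60, 150, 240, 90, 210), c(60, 90, 150, 230, 240))
  for (i in seq_len(nrow(centres)))
    img <- img + runif(1, 2.5, 4) *
      exp(-outer((xs - centres[i, 1])^2, (xs - centres[i, 2])^2, "+") /
            (2 * 9^2))
  prev_px <- Inf; prev_n <- Inf
  for (t in c(2.5, 3, 3.5, 4, 5)) {
    seg <- segment_plaques(img, threshold_sigmas = t, spacing = c(px, px),
                           pre_smooth = 1, size_range = c(5, 100))
    n_px <- sum(seg$labels > 0)
    expect_lte(n_px, prev_px)
    expect_lte(nrow(seg$table), prev_n)
    prev_px <- n_px; prev_n <- nrow(seg$table)
  }
})

test_that("segmentation recovers Poisson-placed plaque counts", {
  ## 20 seeded phantoms at 23/mm2 over 1 mm2; the recovered count should
  ## fall in the central 95% Poisson interval in >= 90% of repetitions
  lo <- qpois(0.025, 23); hi <- qpois(0.975, 23)
  inside <- 0L
  for (s in 1:20) {
    ph <- build_phantom("aged_mouse", seed = 400 + s,
                        extent = c(1000, 1000), slab = 72,
                        voxel = c(5, 5, 2.5))
    seg <- segment_plaques(phantom_enface(ph, 0, 50), pre_smooth = 0)
    n <- nrow(seg$table)
    if (n >= lo && n <= hi) inside <- inside + 1L
  }
  expect_gte(inside, 18L)
})
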