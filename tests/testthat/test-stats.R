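test_that("the KS statistic behaves at its extremes", {
  r0 <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic_D, 0)
  expect_equal(r0$p_raw, 1)
  r1 <- ks_two_sample(c(1, 2), c(3, 4))
  expect_equal(r1$statistic_D, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("exact small-sample p-values match full enumeration", {
  set.seed(61)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(5)
    r <- ks_two_sample(a, b)
    expect_identical(r$method, "exact")
    ## brute-force enumeration over all C(10,5) label assignments
    pool <- c(a, b)
    Ds <- apply(combn(10, 5), 2, function(ix) {
      x <- pool[ix]; y <- pool[-ix]
      max(abs(vapply(sort(pool), function(v) mean(x <= v) - mean(y <= v),
                     0)))
    })
    expect_equal(r$p_raw, mean(Ds >= r$statistic_D - 1e-12),
                 tolerance = 1e-12)
    ## and agree with the independent stats::ks.test implementation
    expect_equal(r$statistic_D, unname(ks.test(a, b)$statistic),
                 tolerance = 1e-12)
    expect_equal(r$p_raw, ks.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("large samples use the asymptotic Kolmogorov distribution", {
  set.seed(62)
  a <- rnorm(80); b <- rnorm(90)
  r <- ks_two_sample(a, b)
  expect_identical(r$method, "asymptotic")
  expect_equal(r$statistic_D, unname(ks.test(a, b)$statistic),
               tolerance = 1e-12)
  ## asymptotic p agrees with ks.test's asymptotic option
  expect_equal(r$p_raw, ks.test(a, b, exact = FALSE)$p.value,
               tolerance = 0.02)
})

test_that("D is invariant under strictly increasing transforms", {
  set.seed(63)
  a <- rlnorm(40); b <- rlnorm(35, 0.4)
  d1 <- ks_two_sample(a, b)$statistic_D
  d2 <- ks_two_sample(log(a), log(b))$statistic_D
  d3 <- ks_two_sample(a^3, b^3)$statistic_D
  expect_equal(d1, d2, tolerance = 1e-12)
  expect_equal(d1, d3, tolerance = 1e-12)
})

test_that("Bonferroni adjustment caps and scales correctly", {
  expect_equal(bonferroni_adjust(c(0.01, 0.04), m = 2), c(0.02, 0.08))
  expect_equal(bonferroni_adjust(0.37, m = 1), 0.37)
  expect_equal(bonferroni_adjust(0.9, m = 3), 1)
  expect_error(bonferroni_adjust(c(0.1, 1.2), 2), "0, 1")
  expect_error(bonferroni_adjust(c(0.1, 0.2, 0.3), m = 2), "at least")
  ## never decreases, never exceeds 1
  set.seed(64)
  p <- runif(50)
  padj <- bonferroni_adjust(p, m = 7 + 50)
  expect_true(all(padj >= p))
  expect_true(all(padj <= 1))
})

test_that("percent increases reproduce the printed plaque-load figures", {
  expect_identical(percent_increase(17, 23), 35)
  expect_identical(percent_increase(16, 24), 50)
  expect_identical(percent_increase(5, 5), 0)
  expect_error(percent_increase(0, 5), "reference")
  expect_equal(percent_increase(17, 23, digits = NULL), 600 / 17,
               tolerance = 1e-12)
})

test_that("group summaries report the standard descriptive statistics", {
  gs <- summarize_group(c(10, 20, 30), bin_edges = seq(0, 40, 10))
  expect_equal(gs$mean, 20)
  expect_equal(gs$sd, 10)
  expect_identical(sum(gs$histogram$counts), 3L)
  expect_equal(gs$fivenum, fivenum(c(10, 20, 30)))
  g0 <- summarize_group(numeric(0))
  expect_identical(g0$n, 0L)
  expect_true(is.na(g0$mean))
  expect_true(all(g0$histogram$counts == 0L))
  expect_error(summarize_group(1:3, bin_edges = c(1, 1, 2)), "increasing")
})

test_that("generated plaque diameters follow the configured lognormal", {
  ## pool truth diameters from large phantoms and compare against the
  ## truncated-lognormal CDF oracle
  d <- unlist(lapply(1:3, function(s)
    build_phantom(fixture("aged_mouse", cells = FALSE), seed = 500 + s,
                  extent = c(2500, 2500), slab = 72,
                  voxel = c(25, 25, 12))$plaque_truth$diameter_um))
  expect_gt(length(d), 300)
  fx <- fixture("aged_mouse")
  plo <- plnorm(10, fx$diameter_meanlog, fx$diameter_sdlog)
  phi <- plnorm(70, fx$diameter_meanlog, fx$diameter_sdlog)
  cdf <- function(q) (plnorm(q, fx$diameter_meanlog, fx$diameter_sdlog) -
                        plo) / (phi - plo)
  expect_gt(ks.test(d, cdf)$p.value, 0.01)
})

test_that("histogram counts sum to n for in-range samples", {
  set.seed(65)
  v <- runif(200, 10, 70)
  gs <- summarize_group(v)
  expect_identical(sum(gs$histogram$counts), 200L)
})
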