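#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx fft mvfft rnorm runif rlnorm rpois median mad
#'   sd var fivenum quantile runmed qpois p.adjust
#' @importFrom utils head tail read.csv write.csv modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Full width at half maximum of a sampled non-negative curve with a single
## dominant peak, by linear interpolation of the half-maximum crossings.
## x may be omitted for unit spacing. Returns width in units of x.
fwhm_interp <- function(y, x = seq_along(y)) {
  i0 <- which.max(y)
  if (i0 == 1L || i0 == length(y))
    stop("peak lies at the array boundary; FWHM undefined", call. = FALSE)
  half <- y[i0] / 2
  ## left crossing
  il <- i0
  while (il > 1L && y[il - 1L] >= half) il <- il - 1L
  if (il == 1L && y[1L] >= half)
    stop("peak not resolved from the left boundary", call. = FALSE)
  xl <- x[il - 1L] + (half - y[il - 1L]) / (y[il] - y[il - 1L]) *
    (x[il] - x[il - 1L])
  ## right crossing
  ir <- i0
  n <- length(y)
  while (ir < n && y[ir + 1L] >= half) ir <- ir + 1L
  if (ir == n && y[n] >= half)
    stop("peak not resolved from the right boundary", call. = FALSE)
  xr <- x[ir] + (half - y[ir]) / (y[ir + 1L] - y[ir]) * (x[ir + 1L] - x[ir])
  xr - xl
}

## Column-wise cumulative sum of a matrix (rows = axial samples), as a
## single lower-triangular matrix product so it vectorizes over columns.
col_cumsum <- function(m) {
  n <- nrow(m)
  L <- matrix(0, n, n)
  L[lower.tri(L, diag = TRUE)] <- 1
  L %*% m
}

## 3x3 median filter on a matrix, edges replicated.
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(m)
  pad <- m[c(1L, 1L:nr, nr), c(1L, 1L:nc, nc)]
  sh <- vector("list", 9L)
  idx <- 1L
  for (di in 0:2) for (dj in 0:2) {
    sh[[idx]] <- pad[(1L + di):(nr + di), (1L + dj):(nc + dj)]
    idx <- idx + 1L
  }
  arr <- array(unlist(sh, use.names = FALSE), dim = c(nr, nc, 9L))
  apply(arr, c(1, 2), median)
}

## Quadratic (3-point) sub-sample interpolation of a peak position.
## Returns offset in [-0.5, 0.5] relative to the central sample.
quad_peak_offset <- function(ym1, y0, yp1) {
  if (!all(is.finite(c(ym1, y0, yp1)))) return(0)
  den <- ym1 - 2 * y0 + yp1
  if (abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  clamp(off, -0.5, 0.5)
}

## Mean (box) filter of half-width r applied separably along every array
## dimension; edges renormalized. Used to pre-smooth before thresholding.
box_smooth <- function(a, r = 1L) {
  if (r < 1L) return(a)
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  smooth_cols <- function(m, r) {
    ## box filter along rows of a matrix, vectorized over columns
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2L, cumsum))
    i1 <- pmax(seq_len(n) - r, 1L); i2 <- pmin(seq_len(n) + r, n)
    (cs[i2 + 1L, , drop = FALSE] - cs[i1, , drop = FALSE]) / (i2 - i1 + 1L)
  }
  if (length(d) == 1L) return(drop(smooth_cols(cbind(a), r)))
  out <- a
  for (k in seq_along(d)) {
    perm <- c(k, setdiff(seq_along(d), k))
    tmp <- aperm(out, perm)
    dp <- dim(tmp)
    tmp <- smooth_cols(matrix(tmp, nrow = dp[1L]), r)
    dim(tmp) <- dp
    out <- aperm(tmp, order(perm))
  }
  out
}
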