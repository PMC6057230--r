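## ---- group statistics --------------------------------------------------

## Exact two-sample KS p-value P(D >= d) for untied samples, by counting
## monotone lattice paths from (0,0) to (n1,n2) that stay strictly inside
## the band |i/n1 - j/n2| < d (Hodges' algorithm). Exact and O(n1 * n2).
ks_exact_p <- function(d, n1, n2) {
  ## number of orderings with sup|ECDF difference| < d
  u <- matrix(0, n1 + 1L, n2 + 1L)
  u[1L, 1L] <- 1
  for (i in 0:n1) for (j in 0:n2) {
    if (i == 0L && j == 0L) next
    if (abs(i / n1 - j / n2) >= d - 1e-12) { u[i + 1L, j + 1L] <- 0; next }
    acc <- 0
    if (i > 0L) acc <- acc + u[i, j + 1L]
    if (j > 0L) acc <- acc + u[i + 1L, j]
    u[i + 1L, j + 1L] <- acc
  }
  1 - u[n1 + 1L, n2 + 1L] / choose(n1 + n2, n1)
}

## Asymptotic Kolmogorov survival function Q(lambda) = P(sqrt(n) D > lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-10) return(1)
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  clamp(p, 0, 1)
}

#' Two-sample Kolmogorov--Smirnov test
#'
#' Computes `D = sup |ECDF_a - ECDF_b|` and its p-value: exactly (by
#' lattice-path enumeration, valid for untied data) when both samples
#' have at most `exact_max` observations, otherwise from the asymptotic
#' Kolmogorov distribution evaluated at
#' `sqrt(n1 n2 / (n1 + n2)) * D`.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @param alpha significance level recorded in the report.
#' @param comparisons_m size of the comparison family for the Bonferroni
#'   adjustment recorded in the report.
#' @param exact_max exact-p size cutoff per group.
#' @param test_name label stored in the report.
#' @return A `stat_report`: test_name, statistic_D, p_raw, p_adjusted,
#'   n1, n2, alpha, comparisons_m, method.
#' @examples
#' ks_two_sample(c(1, 2), c(3, 4))$statistic_D   # 1: disjoint supports
#' @export
ks_two_sample <- function(sample_a, sample_b, alpha = 0.05,
                          comparisons_m = 1L, exact_max = 10L,
                          test_name = "two-sample KS") {
  if (!length(sample_a) || !length(sample_b))
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b)))
    stop("samples must be finite", call. = FALSE)
  n1 <- length(sample_a); n2 <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  ord <- order(pooled)
  z <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  ## with ties, only the ECDF difference at distinct values counts
  dup <- duplicated(sort(pooled), fromLast = TRUE)
  D <- max(abs(z[!dup]), 0)
  method <- if (n1 <= exact_max && n2 <= exact_max) "exact" else "asymptotic"
  p <- if (method == "exact") {
    ks_exact_p(D, n1, n2)
  } else {
    kolmogorov_sf(sqrt(n1 * n2 / (n1 + n2)) * D)
  }
  structure(list(test_name = test_name, statistic_D = D, p_raw = p,
                 p_adjusted = min(1, comparisons_m * p), n1 = n1, n2 = n2,
                 alpha = alpha, comparisons_m = comparisons_m,
                 method = method),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat(sprintf(
    "%s: D = %.4f, p = %.4g (%s), Bonferroni (m = %d): p = %.4g [n = %d, %d]\n",
    x$test_name, x$statistic_D, x$p_raw, x$method, x$comparisons_m,
    x$p_adjusted, x$n1, x$n2))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' `p -> min(1, m p)` for a declared family of `m` comparisons.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param m family size, at least `length(p_values)`.
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(c(0.01, 0.04), m = 2)
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) ||
      any(is.na(p_values)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values))
    stop("'m' must be at least the number of p-values", call. = FALSE)
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Percent increase relative to a reference
#'
#' `100 (comparison - reference) / reference`, reported rounded to the
#' nearest integer percent by default (17 -> 23 plaques/mm2 is a 35%
#' increase; 16 -> 24 is 50%).
#'
#' @param reference positive reference value.
#' @param comparison non-negative comparison value.
#' @param digits rounding digits (`NULL` for unrounded).
#' @return percent increase.
#' @examples
#' percent_increase(17, 23)   # 35
#' percent_increase(16, 24)   # 50
#' @export
percent_increase <- function(reference, comparison, digits = 0) {
  stopifnot_scalar_num(reference, "reference", lower = .Machine$double.xmin)
  stopifnot_scalar_num(comparison, "comparison", lower = 0)
  out <- 100 * (comparison - reference) / reference
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Descriptive group summary
#'
#' Mean, SD (n - 1 denominator), Tukey five-number summary and a
#' histogram on fixed bin edges (right-open bins, last bin closed), as
#' used for plaque-diameter distributions.
#'
#' @param values numeric vector (may be empty).
#' @param bin_edges increasing bin edges in um (default 5-um bins over
#'   the 10--70 um plaque-diameter range).
#' @param label group label.
#' @return A `group_summary`: label, n, mean, sd, fivenum, histogram
#'   (`breaks`, `counts`). Empty input gives `n = 0`, `NA` summaries and
#'   all-zero counts.
#' @export
summarize_group <- function(values, bin_edges = seq(10, 70, by = 5),
                            label = "group") {
  if (any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges) - 1L
  if (!length(values)) {
    return(structure(list(label = label, n = 0L, mean = NA_real_,
                          sd = NA_real_, fivenum = rep(NA_real_, 5L),
                          histogram = list(breaks = bin_edges,
                                           counts = integer(nb))),
                     class = "group_summary"))
  }
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  structure(list(label = label, n = length(values), mean = mean(values),
                 sd = sd(values), fivenum = fivenum(values),
                 histogram = list(breaks = bin_edges, counts = counts)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("group_summary '%s': n = %d, mean = %.3g, sd = %.3g\n",
              x$label, x$n, x$mean, x$sd))
  invisible(x)
}
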