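# Thin, validated wrappers over the classical tests used in the reports:
# exact two-sided binomial, Fisher's exact test on 2x2 tables with the
# sample (cross-product) odds ratio, chi-squared with and without Yates
# correction, and Bonferroni adjustment.

#' Exact two-sided binomial test of up- vs down-regulated counts
#'
#' Tests the null that increases and decreases are equally likely
#' (p = 0.5) given `k_up` events up and `k_down` events down.
#'
#' @param k_up,k_down Non-negative counts; at least one must be positive.
#' @return List: `k_up`, `k_down`, `n`, `p_value`.
#' @export
binomial_two_sided <- function(k_up, k_down) {
  if (k_up < 0 || k_down < 0) stop("counts must be non-negative")
  n <- k_up + k_down
  if (n == 0) stop("both counts are zero; nothing to test")
  ht <- stats::binom.test(k_up, n, p = 0.5, alternative = "two.sided")
  list(k_up = k_up, k_down = k_down, n = n, p_value = ht$p.value)
}

#' Fisher's exact test on a 2x2 table with the sample odds ratio
#'
#' The reported odds ratio is the sample cross-product (a*d)/(b*c) computed
#' from the table (0 or Inf when a zero cell makes it degenerate), not the
#' conditional maximum-likelihood estimate `fisher.test()` reports; set
#' `cmle = TRUE` to get the CMLE as well.
#'
#' @param tab 2x2 matrix or something coercible to one.
#' @param cmle Also return the conditional MLE odds ratio (default FALSE).
#' @return List: `odds_ratio`, `p_value`, and `odds_ratio_cmle` if requested.
#' @export
fisher_2x2 <- function(tab, cmle = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("table has a zero margin; the test is undefined")
  }
  ht <- stats::fisher.test(tab)
  a <- tab[1L, 1L]; b <- tab[1L, 2L]; c_ <- tab[2L, 1L]; d <- tab[2L, 2L]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  out <- list(odds_ratio = or, p_value = ht$p.value)
  if (cmle) out$odds_ratio_cmle <- unname(ht$estimate)
  out
}

#' Chi-squared test on a 2x2 table with Yates continuity correction
#'
#' @param tab 2x2 matrix.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
chi2_2x2_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson chi-squared test on an r x c table (no continuity correction)
#'
#' Errors if any expected cell count is zero, naming the offending cell.
#'
#' @param tab Matrix of counts.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi2_rxc <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1L, ]
    stop("expected count is zero in cell [", bad[1L], ", ", bad[2L],
         "]; drop the empty row/column before testing")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, expected = expected)
}

#' Bonferroni adjustment
#'
#' @param p Vector of p-values.
#' @param m Number of tests in the family (default `length(p)`; must be at
#'   least `length(p)`).
#' @return Adjusted p-values `pmin(1, p * m)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= length(p)")
  pmin(1, p * m)
}
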