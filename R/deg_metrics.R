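#' Exact Poisson-ratio test for a pair of tag counts
#'
#' The conditional (Audic-Claverie) test for comparing one count per
#' library without replicates.  Given `x` tags in a library of `N1`
#' mapped fragments, the count `y` in a library of `N2` fragments has the
#' conditional distribution
#' `P(Y = y | x) = r^y (x+y)! / (x! y! (1+r)^(x+y+1))` with `r = N2/N1`,
#' i.e. a negative binomial with size `x + 1` and success probability
#' `N1/(N1+N2)`.  The two-sided p-value doubles the smaller tail
#' (point-inclusive) and is capped at 1.
#'
#' @param x,y non-negative tag counts in the two libraries.
#' @param N1,N2 total uniquely mapped fragments of the two libraries
#'   (> 0).
#' @return two-sided p-values, vectorised over the inputs.
#' @examples
#' metric_poisson_ratio(5, 5, 1e6, 1e6) # 1
#' metric_poisson_ratio(0, 20, 1e6, 1e6)
#' @export
metric_poisson_ratio <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(N1 <= 0) || any(N2 <= 0)) {
    stop("library totals must be positive", call. = FALSE)
  }
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  N1 <- rep_len(N1, n)
  N2 <- rep_len(N2, n)
  prob <- N1 / (N1 + N2)
  lower <- pnbinom(y, size = x + 1, prob = prob)
  upper <- pnbinom(y - 1, size = x + 1, prob = prob,
    lower.tail = FALSE
  )
  pmin(1, 2 * pmin(lower, upper))
}

#' Fisher's exact test on tag-count proportions
#'
#' Two-sided Fisher exact p-value on the 2x2 table
#' `[[x, N1 - x], [y, N2 - y]]`: a second no-replicate metric for the
#' consensus, testing whether a transcript's share of tags differs
#' between the libraries.
#'
#' @inheritParams metric_poisson_ratio
#' @return two-sided p-values, vectorised.
#' @export
metric_fisher <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(N1 <= 0) || any(N2 <= 0) || any(x > N1) || any(y > N2)) {
    stop("counts must not exceed their library totals", call. = FALSE)
  }
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  N1 <- rep_len(N1, n)
  N2 <- rep_len(N2, n)
  p <- vapply(seq_len(n), function(i) {
    fisher.test(matrix(
      c(x[i], N1[i] - x[i], y[i], N2[i] - y[i]),
      nrow = 2, byrow = TRUE
    ))$p.value
  }, numeric(1))
  # fisher.test can exceed 1 by floating-point error
  pmin(1, p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) n / j`, capped at 1 and
#' returned in the input order.  This is the `p.adjust(method = "BH")`
#' procedure; inputs are validated to lie in `[0, 1]`.
#'
#' @param p raw p-values in `[0, 1]` (NAs preserved).
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
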