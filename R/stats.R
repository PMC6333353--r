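# Shared statistical primitives.

#' Chi-square goodness-of-fit on counts
#'
#' Statistic \eqn{\sum (O-E)^2/E} with k-1 degrees of freedom and an
#' upper-tail p-value. The expected vector may be any positive reals
#' (it is not renormalized), so expectations derived from an external
#' reference can be tested directly.
#'
#' @param observed non-negative counts, length >= 2.
#' @param expected positive expected values, same length.
#' @return list (class `tapfree_test`): `statistic`, `df`, `p`, `method`,
#'   `warnings` (character; flags `low_expected` when any E < 5).
#' @export
chi_square_gof <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), length(observed) >= 2L)
  if (any(observed < 0)) stop("negative observed counts")
  if (any(expected <= 0)) stop("expected values must be positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  warn <- if (any(expected < 5)) "low_expected" else character(0)
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "chi2_gof", warnings = warn),
            class = "tapfree_test")
}

# One-cell chi-square (1 df): observed-vs-rest against expected-vs-rest.
chi_square_cell <- function(observed, expected, total) {
  stat <- (observed - expected)^2 / expected +
    ((total - observed) - (total - expected))^2 / (total - expected)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Two-sample t-test (pooled or Welch), two-tailed
#'
#' Wraps [stats::t.test()] and handles the degenerate zero-variance cases
#' explicitly: equal means with zero variance in both samples give p = 1;
#' unequal means with zero variance give p = 0 with a `degenerate` flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param mode `pooled` (classic Student, default) or `welch`.
#' @return list (class `tapfree_test`): `statistic`, `df`, `p`, `method`,
#'   `warnings`.
#' @export
two_sample_t <- function(a, b, mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  method <- if (mode == "pooled") "t_pooled" else "t_welch"
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(statistic = 0, df = NA_real_, p = 1,
                            method = method, warnings = "zero_variance"),
                       class = "tapfree_test"))
    return(structure(list(statistic = sign(mean(a) - mean(b)) * Inf,
                          df = NA_real_, p = 0, method = method,
                          warnings = c("zero_variance", "degenerate")),
                     class = "tapfree_test"))
  }
  tt <- stats::t.test(a, b, var.equal = (mode == "pooled"))
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, method = method, warnings = character(0)),
            class = "tapfree_test")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving.
#' @param pvals numeric vector of p-values in [0, 1].
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' @export
print.tapfree_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              ifelse(is.na(x$df), "NA", format(x$df)), x$p))
  if (length(x$warnings)) cat("flags:", paste(x$warnings, collapse = ", "), "\n")
  invisible(x)
}
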