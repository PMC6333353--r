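# Positional decile mapping of ligands on their parental proteins.

#' Decile of a peptide within its parent
#'
#' The peptide midpoint m = (start + end) / 2 is mapped to
#' ceiling(10 m / L), clamped to [1, 10], so a peptide "lives" in the decile
#' containing its midpoint.
#'
#' @param start,end 1-based inclusive peptide coordinates (vectorized).
#' @param L parent protein length(s).
#' @return integer decile in 1..10.
#' @export
assign_decile <- function(start, end, L) {
  if (any(start < 1 | end > L | start > end))
    stop("coordinates outside [1, L]")
  m <- (start + end) / 2
  d <- ceiling(10 * m / L)
  pmin(pmax(d, 1L), 10L)
}

#' Positional profile of a dataset
#'
#' Weighted decile histogram of all occurrences plus weighted counts of
#' exact-N-terminal (start == 1) and exact-C-terminal (end == L) ligands.
#'
#' @param collection a `ligand_collection`.
#' @param dataset dataset label.
#' @return object of class `positional_profile`: list with `dataset`,
#'   `decile_counts` (length 10), `n_exact_N`, `n_exact_C`, `n_total`.
#' @export
positional_profile <- function(collection, dataset) {
  occ <- collection$occurrences
  occ <- occ[occ$dataset == dataset, , drop = FALSE]
  if (!nrow(occ)) stop("empty or unknown dataset: ", dataset)
  L <- collection$proteins$length[match(occ$protein_id,
                                        collection$proteins$id)]
  dec <- assign_decile(occ$start, occ$end, L)
  counts <- vapply(1:10, function(d) sum(occ$weight[dec == d]), numeric(1))
  structure(list(
    dataset = dataset,
    decile_counts = counts,
    n_exact_N = sum(occ$weight[occ$start == 1L]),
    n_exact_C = sum(occ$weight[occ$end == L]),
    n_total = sum(occ$weight)),
    class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat("Positional profile:", x$dataset, sprintf("(n = %.1f)\n", x$n_total))
  pct <- 100 * x$decile_counts / x$n_total
  cat("decile %:", paste(sprintf("%.1f", pct), collapse = " "), "\n")
  cat(sprintf("exact N-terminal: %.1f%%   exact C-terminal: %.1f%%\n",
              100 * x$n_exact_N / x$n_total, 100 * x$n_exact_C / x$n_total))
  invisible(x)
}

#' Chi-square test of decile counts against uniform placement
#'
#' Goodness-of-fit of the 10 decile counts against the uniform expectation
#' n/10 per bin (df = 9).
#'
#' @param profile a `positional_profile`.
#' @param min_total minimum weighted peptide count required (default 50).
#' @return a `tapfree_test` (see [chi_square_gof()]).
#' @export
decile_uniformity_test <- function(profile, min_total = 50) {
  if (profile$n_total < min_total)
    stop("fewer than ", min_total, " peptides; test not run")
  chi_square_gof(profile$decile_counts, rep(profile$n_total / 10, 10))
}
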