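# Position-specific residue composition of parental-protein termini.

#' Position-specific residue composition of protein termini
#'
#' For the C-terminal end, position 1 is the LAST residue of the sequence
#' and position w the w-th residue from the end; for the N-terminal end,
#' position 1 is the first residue. Each protein contributes once; proteins
#' shorter than the window contribute only to the positions they cover, so
#' every position carries its own denominator.
#'
#' @param seqs character vector of protein sequences (unique proteins).
#' @param end `"C"` or `"N"`.
#' @param window number of positions to profile (default 20).
#' @return object of class `terminal_composition`: list with `end`,
#'   `window`, `freq` (window x 20 matrix of frequencies, rows = positions),
#'   `counts` (raw counts), `n_at_position` (denominator per position),
#'   `n_proteins`.
#' @export
terminal_composition <- function(seqs, end = c("C", "N"), window = 20L) {
  end <- match.arg(end)
  stopifnot(window >= 1L, length(seqs) >= 1L)
  counts <- matrix(0, nrow = window, ncol = length(AA_ALPHABET),
                   dimnames = list(position = seq_len(window),
                                   residue = AA_ALPHABET))
  n_at <- integer(window)
  lens <- nchar(seqs)
  for (pos in seq_len(window)) {
    covered <- lens >= pos
    idx <- if (end == "C") lens[covered] - pos + 1L else pos
    res <- substr(seqs[covered], idx, idx)
    res <- res[res %in% AA_ALPHABET]  # 'X' excluded from both sides
    tab <- table(factor(res, levels = AA_ALPHABET))
    counts[pos, ] <- as.numeric(tab)
    n_at[pos] <- length(res)
  }
  freq <- counts / ifelse(n_at > 0, n_at, 1)
  structure(list(end = end, window = window, freq = freq, counts = counts,
                 n_at_position = n_at, n_proteins = length(seqs)),
            class = "terminal_composition")
}

#' @export
print.terminal_composition <- function(x, ...) {
  cat(sprintf("Terminal composition: %s-end, window %d, %d proteins\n",
              x$end, x$window, x$n_proteins))
  invisible(x)
}

#' Compare a residue-class frequency between two terminal compositions
#'
#' Computes the per-position frequency of a residue class in each matrix
#' over a position range, the mean class frequency in each, and a two-tailed
#' t-test treating positions as paired observations. A per-position
#' chi-square on the raw counts is reported alongside.
#'
#' @param matA,matB `terminal_composition` objects with the same end and
#'   window convention.
#' @param residue_class residues forming the class (e.g. `"G"`,
#'   `c("F","W","Y")`), or the name of an entry of [RESIDUE_CLASSES].
#' @param positions integer positions to compare (default the full window).
#' @return object of class `composition_comparison`: list with `per_position`
#'   (position, freq_a, freq_b, chi2, p), `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_composition <- function(matA, matB, residue_class,
                                positions = NULL) {
  stopifnot(matA$end == matB$end)
  if (is.character(residue_class) && length(residue_class) == 1L &&
      residue_class %in% names(RESIDUE_CLASSES))
    residue_class <- RESIDUE_CLASSES[[residue_class]]
  stopifnot(all(residue_class %in% AA_ALPHABET))
  if (is.null(positions))
    positions <- seq_len(min(matA$window, matB$window))
  if (any(positions < 1 | positions > matA$window |
          positions > matB$window))
    stop("positions outside the window")

  fa <- rowSums(matA$freq[positions, residue_class, drop = FALSE])
  fb <- rowSums(matB$freq[positions, residue_class, drop = FALSE])

  pp <- do.call(rbind, lapply(seq_along(positions), function(i) {
    pos <- positions[i]
    oa <- sum(matA$counts[pos, residue_class]); na <- matA$n_at_position[pos]
    ob <- sum(matB$counts[pos, residue_class]); nb <- matB$n_at_position[pos]
    chi <- if (na > 0 && nb > 0 && (oa + ob) > 0 &&
               (na - oa + nb - ob) > 0) {
      suppressWarnings(stats::chisq.test(
        matrix(c(oa, na - oa, ob, nb - ob), nrow = 2), correct = FALSE))
    } else NULL
    data.frame(position = pos, freq_a = fa[i], freq_b = fb[i],
               chi2 = if (is.null(chi)) NA_real_ else unname(chi$statistic),
               p = if (is.null(chi)) NA_real_ else chi$p.value,
               stringsAsFactors = FALSE)
  }))

  if (length(positions) >= 2L && stats::sd(fa - fb) > 0) {
    tt <- stats::t.test(fa, fb, paired = TRUE)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else if (all(fa == fb)) {
    t <- 0; df <- length(positions) - 1; p <- 1
  } else {
    t <- NA_real_; df <- NA_real_; p <- NA_real_
  }
  structure(list(per_position = pp, mean_a = mean(fa), mean_b = mean(fb),
                 t = t, df = df, p = p,
                 residue_class = residue_class, positions = positions),
            class = "composition_comparison")
}

#' @export
print.composition_comparison <- function(x, ...) {
  cat(sprintf(
    "Class {%s}, positions %d-%d: mean %.2f%% vs %.2f%% (paired t = %.3g, p = %.3g)\n",
    paste(x$residue_class, collapse = ","), min(x$positions),
    max(x$positions), 100 * x$mean_a, 100 * x$mean_b, x$t, x$p))
  invisible(x)
}
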