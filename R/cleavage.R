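# Cleavage-site flanking residues (Schechter-Berger P3-P3') and
# background-normalized enrichment.

#' Flanking residues of both scissile bonds of one ligand
#'
#' The N-cut lies between parent positions start-1 and start: P1-P3 are the
#' parent residues immediately upstream of the cut and P1'-P3' the first
#' peptide residues. The C-cut lies between end and end+1: P1-P3 are the
#' last peptide residues and P1'-P3' the parent residues downstream.
#' Positions beyond the sequence bounds are NA (ABSENT). A peptide starting
#' at position 1 has no N-cut hydrolysis event, and one ending at the exact
#' C-terminus no C-cut; the corresponding site is returned as all-NA and is
#' excluded from counting.
#'
#' @param start,end 1-based inclusive occurrence coordinates.
#' @param seq parent protein sequence.
#' @return list with `N` and `C`, each a named character vector over
#'   positions P3, P2, P1, P1', P2', P3' (NA = absent).
#' @export
extract_flanks <- function(start, end, seq) {
  L <- nchar(seq)
  stopifnot(start >= 1L, end <= L, start <= end)
  res_at <- function(i)
    if (i >= 1L && i <= L) substr(seq, i, i) else NA_character_
  ncut <- if (start == 1L) rep(NA_character_, 6L) else
    vapply(c(start - 3L, start - 2L, start - 1L, start, start + 1L,
             start + 2L), res_at, character(1))
  ccut <- if (end == L) rep(NA_character_, 6L) else
    vapply(c(end - 2L, end - 1L, end, end + 1L, end + 2L, end + 3L),
           res_at, character(1))
  names(ncut) <- names(ccut) <- FLANK_POSITIONS
  list(N = ncut, C = ccut)
}

#' Pooled residue frequencies of a protein set
#'
#' Background residue occurrence over the full sequences; 'X' and other
#' non-standard letters are ignored.
#'
#' @param seqs character vector of protein sequences.
#' @return named numeric vector over the 20 residues, summing to 1.
#' @export
compute_background <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  aa <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  tab <- table(factor(aa[aa %in% AA_ALPHABET], levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab) / sum(tab), AA_ALPHABET)
}

#' Weighted flank-residue counts for a dataset
#'
#' Tallies residues at every defined P3-P3' position of the N-cut and C-cut
#' sites of all occurrences of a dataset, weighted by occurrence weight.
#' Sites whose cut does not exist (exact-terminal peptides) are excluded;
#' sites close to a protein end contribute only to the positions they
#' define, so each position carries its own site denominator.
#'
#' @param collection a `ligand_collection`.
#' @param dataset dataset label.
#' @param background_scope `"dataset"` (default: residue background from the
#'   dataset's own parental proteins) or `"proteome"` (all proteins).
#' @return object of class `flank_count_table`: list with `dataset`,
#'   `counts` (data.frame cut x position x residue weighted counts),
#'   `n_sites` (data.frame cut x position weighted site counts),
#'   `background` (residue frequency vector).
#' @export
flank_counts <- function(collection, dataset,
                         background_scope = c("dataset", "proteome")) {
  background_scope <- match.arg(background_scope)
  occ <- collection$occurrences
  occ <- occ[occ$dataset == dataset, , drop = FALSE]
  if (!nrow(occ)) stop("empty or unknown dataset: ", dataset)
  prot <- collection$proteins
  seqs <- prot$seq[match(occ$protein_id, prot$id)]
  L <- nchar(seqs)

  # vectorized residue extraction per cut/position
  grab <- function(idx) {
    r <- substr(seqs, idx, idx)
    r[idx < 1L | idx > L | r == ""] <- NA
    r[!is.na(r) & !r %in% AA_ALPHABET] <- NA
    r
  }
  offs <- list(
    N = list(P3 = occ$start - 3L, P2 = occ$start - 2L, P1 = occ$start - 1L,
             `P1'` = occ$start, `P2'` = occ$start + 1L,
             `P3'` = occ$start + 2L),
    C = list(P3 = occ$end - 2L, P2 = occ$end - 1L, P1 = occ$end,
             `P1'` = occ$end + 1L, `P2'` = occ$end + 2L,
             `P3'` = occ$end + 3L))
  exists_cut <- list(N = occ$start > 1L, C = occ$end < L)

  rows <- list(); srows <- list()
  for (cut in c("N", "C")) {
    for (pos in FLANK_POSITIONS) {
      r <- grab(offs[[cut]][[pos]])
      ok <- exists_cut[[cut]] & !is.na(r)
      w <- occ$weight[ok]
      if (length(w)) {
        agg <- vapply(split(w, r[ok]), sum, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          cut = cut, position = pos, residue = names(agg),
          count = as.numeric(agg), stringsAsFactors = FALSE)
      }
      srows[[length(srows) + 1L]] <- data.frame(
        cut = cut, position = pos, n_sites = sum(w),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, rows)
  n_sites <- do.call(rbind, srows)
  rownames(counts) <- rownames(n_sites) <- NULL

  bg_seqs <- if (background_scope == "dataset")
    prot$seq[prot$id %in% unique(occ$protein_id)] else prot$seq
  structure(list(dataset = dataset, counts = counts, n_sites = n_sites,
                 background = compute_background(bg_seqs)),
            class = "flank_count_table")
}

#' @export
print.flank_count_table <- function(x, ...) {
  cat("Flank counts:", x$dataset, "\n")
  print(x$n_sites)
  invisible(x)
}

#' Background-normalized residue enrichment at cleavage flanks
#'
#' For every (cut, position, residue) and for grouped biochemical classes:
#' expected = background frequency x number of sites; ratio =
#' observed/expected; one-degree chi-square of observed-vs-rest against
#' expected-vs-rest; significance = (ratio >= fold_min) AND (p < alpha).
#'
#' @param table a `flank_count_table`.
#' @param min_sites positions with fewer (weighted) sites are skipped
#'   (default 20).
#' @param fold_min fold-enrichment threshold (default 2).
#' @param alpha p-value threshold (default 0.001).
#' @return data.frame (class `flank_enrichment`): `cut`, `position`,
#'   `unit_type` (residue/class), `unit`, `observed`, `expected`, `ratio`,
#'   `chi2`, `p`, `significant`.
#' @export
flank_enrichment <- function(table, min_sites = 20, fold_min = 2,
                             alpha = 0.001) {
  bg <- table$background
  class_bg <- vapply(RESIDUE_CLASSES, function(cl) sum(bg[cl]), numeric(1))
  out <- list()
  for (i in seq_len(nrow(table$n_sites))) {
    cut <- table$n_sites$cut[i]; pos <- table$n_sites$position[i]
    n <- table$n_sites$n_sites[i]
    if (n < min_sites) next
    sub <- table$counts[table$counts$cut == cut &
                          table$counts$position == pos, , drop = FALSE]
    obs_res <- stats::setNames(rep(0, length(AA_ALPHABET)), AA_ALPHABET)
    obs_res[sub$residue] <- sub$count
    obs_cls <- vapply(RESIDUE_CLASSES, function(cl) sum(obs_res[cl]),
                      numeric(1))
    units <- data.frame(
      unit_type = c(rep("residue", length(obs_res)),
                    rep("class", length(obs_cls))),
      unit = c(names(obs_res), names(obs_cls)),
      observed = c(unname(obs_res), unname(obs_cls)),
      bg = c(unname(bg), unname(class_bg)),
      stringsAsFactors = FALSE)
    units$expected <- units$bg * n
    units$ratio <- ifelse(units$expected > 0,
                          units$observed / units$expected,
                          ifelse(units$observed > 0, Inf, NA_real_))
    chi <- mapply(function(o, e) {
      if (e <= 0 || e >= n) return(c(NA_real_, NA_real_))
      ct <- chi_square_cell(o, e, n)
      c(ct$statistic, ct$p)
    }, units$observed, units$expected)
    units$chi2 <- chi[1L, ]
    units$p <- chi[2L, ]
    units$significant <- !is.na(units$ratio) & !is.na(units$p) &
      units$ratio >= fold_min & units$p < alpha
    units$cut <- cut; units$position <- pos
    out[[length(out) + 1L]] <- units[, c("cut", "position", "unit_type",
                                         "unit", "observed", "expected",
                                         "ratio", "chi2", "p",
                                         "significant")]
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cut = character(), position = character(),
                      unit_type = character(), unit = character(),
                      observed = numeric(), expected = numeric(),
                      ratio = numeric(), chi2 = numeric(), p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("flank_enrichment", "data.frame")
  res
}
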