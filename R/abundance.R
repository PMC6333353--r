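# Expression stratification, dataset association and annotation-term
# enrichment.

#' Representation of datasets across mRNA-abundance strata
#'
#' Bins parental proteins (and, weighted, their peptides) by RPKM and
#' compares each dataset's representation above a threshold with a
#' reference set, at the protein and at the peptide level. Proteins without
#' an expression value go to an explicit `unmeasured` stratum that is
#' excluded from the fold computation.
#'
#' @param collection a `ligand_collection` with RPKM values on its proteins.
#' @param reference `"proteome"` (default: every protein in the collection)
#'   or a dataset label (e.g. `"TAP+"`).
#' @param threshold RPKM cut for the fold computation (default 8).
#' @param bin_edges stratum edges (default c(0, 0.5, 1, 2, 4, 8, 16, 32,
#'   Inf)).
#' @return object of class `abundance_representation`: list with `strata`
#'   (per dataset and bin: protein fraction and weighted peptide fraction),
#'   `folds` (per dataset: protein- and peptide-level fold above threshold
#'   vs reference, with chi-square p on protein counts), `reference`,
#'   `threshold`.
#' @export
abundance_representation <- function(collection, reference = "proteome",
                                     threshold = 8,
                                     bin_edges = c(0, 0.5, 1, 2, 4, 8, 16,
                                                   32, Inf)) {
  prot <- collection$proteins
  occ <- collection$occurrences
  labels <- sort(unique(occ$dataset))
  rpkm_of <- stats::setNames(prot$rpkm, prot$id)

  bin_label <- function(r) {
    lab <- as.character(cut(r, breaks = bin_edges, include.lowest = TRUE,
                            right = FALSE))
    lab[is.na(r)] <- "unmeasured"
    lab
  }
  bins <- c(levels(cut(numeric(0), breaks = bin_edges,
                       include.lowest = TRUE, right = FALSE)), "unmeasured")

  ref_ids <- if (identical(reference, "proteome")) prot$id else
    parent_ids(collection, reference)
  ref_rpkm <- rpkm_of[ref_ids]
  ref_measured <- ref_rpkm[!is.na(ref_rpkm)]
  if (!length(ref_measured)) stop("reference set has no expression values")
  ref_frac_above <- mean(ref_measured > threshold)
  # peptide-level reference fraction: the reference dataset's own weighted
  # peptide share above threshold; for the whole proteome, the protein share
  ref_pep_above <- ref_frac_above
  if (!identical(reference, "proteome")) {
    rocc <- occ[occ$dataset == reference, , drop = FALSE]
    rr <- rpkm_of[rocc$protein_id]
    if (any(!is.na(rr)))
      ref_pep_above <- sum(rocc$weight[!is.na(rr) & rr > threshold]) /
        sum(rocc$weight[!is.na(rr)])
  }

  strata <- list(); folds <- list()
  for (d in labels) {
    ids <- parent_ids(collection, d)
    r <- rpkm_of[ids]
    pb <- table(factor(bin_label(r), levels = bins))
    docc <- occ[occ$dataset == d, , drop = FALSE]
    wr <- rpkm_of[docc$protein_id]
    wb <- vapply(split(docc$weight, factor(bin_label(wr), levels = bins)),
                 sum, numeric(1))
    strata[[d]] <- data.frame(
      dataset = d, bin = bins,
      protein_count = as.numeric(pb),
      protein_fraction = as.numeric(pb) / sum(pb),
      peptide_weight = as.numeric(wb),
      peptide_fraction = as.numeric(wb) / sum(wb),
      stringsAsFactors = FALSE)

    meas <- r[!is.na(r)]
    wmeas_w <- docc$weight[!is.na(wr)]
    wmeas_r <- wr[!is.na(wr)]
    if (length(meas) && ref_frac_above > 0) {
      frac_above <- mean(meas > threshold)
      pep_above <- sum(wmeas_w[wmeas_r > threshold]) / sum(wmeas_w)
      obs <- c(sum(meas > threshold), sum(meas <= threshold))
      expd <- c(ref_frac_above, 1 - ref_frac_above) * length(meas)
      chi <- if (all(expd > 0)) chi_square_gof(obs, expd) else
        list(statistic = NA_real_, p = NA_real_)
      folds[[d]] <- data.frame(
        dataset = d,
        n_measured = length(meas),
        fold_protein = frac_above / ref_frac_above,
        fold_peptide = if (ref_pep_above > 0) pep_above / ref_pep_above
                       else NA_real_,
        chi2 = chi$statistic, p = chi$p, stringsAsFactors = FALSE)
    }
  }
  structure(list(strata = do.call(rbind, strata),
                 folds = do.call(rbind, folds),
                 reference = reference, threshold = threshold),
            class = "abundance_representation")
}

#' @export
print.abundance_representation <- function(x, ...) {
  cat(sprintf("Abundance representation (reference: %s, RPKM > %g)\n",
              x$reference, x$threshold))
  if (!is.null(x$folds)) print(x$folds, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Associate parental proteins with datasets
#'
#' A protein is associated with dataset d when all of its peptides fall in
#' d ("strictly contained"), or when its observed share of peptides in d,
#' relative to the share expected from the dataset's size within the whole
#' study, exceeds 2: (c_d / sum(c)) / (size_d / sum(size)) > 2. A protein
#' may associate with zero or several datasets.
#'
#' @param collection a `ligand_collection`.
#' @param ratio_min association ratio threshold (default 2).
#' @return data.frame: `protein_id`, `dataset`, `observed_share`,
#'   `expected_share`, `ratio`, `strictly_contained`, `associated`.
#' @export
assign_exclusive_datasets <- function(collection, ratio_min = 2) {
  occ <- collection$occurrences
  sizes <- collection$dataset_sizes
  labels <- names(sizes)
  expected_share <- sizes / sum(sizes)
  out <- lapply(split(occ, occ$protein_id), function(po) {
    cw <- vapply(labels, function(d) sum(po$weight[po$dataset == d]),
                 numeric(1))
    share <- cw / sum(cw)
    data.frame(protein_id = po$protein_id[1L], dataset = labels,
               observed_share = unname(share),
               expected_share = unname(expected_share),
               ratio = unname(share / expected_share),
               strictly_contained = unname(share == 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$associated <- res$strictly_contained | res$ratio > ratio_min
  res <- res[res$observed_share > 0, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Flat annotation-term enrichment
#'
#' For every term with at least `min_universe` members in the universe:
#' detected count in the protein set, expected count under the universe
#' term fraction, ratio, a chi-square p-value on the 2x2 membership table
#' (or a hypergeometric upper-tail p), and a Benjamini-Hochberg q-value.
#' Results are sorted by p.
#'
#' @param set character vector of protein ids (e.g. proteins associated
#'   with one dataset).
#' @param annotations data.frame `protein_id`, `term_id`, optional `aspect`
#'   (from [read_gaf()]).
#' @param universe character vector of protein ids; must contain `set`.
#' @param min_universe minimum universe members per tested term (default 5).
#' @param method `"chi2"` (default) or `"hypergeometric"`.
#' @return data.frame (class `term_enrichment`): `term_id`, `aspect`,
#'   `detected`, `expected`, `ratio`, `p`, `q`, sorted by p.
#' @export
term_enrichment <- function(set, annotations, universe, min_universe = 5,
                            method = c("chi2", "hypergeometric")) {
  method <- match.arg(method)
  if (!nrow(annotations)) stop("empty annotation set")
  if (!all(set %in% universe)) stop("set must be contained in universe")
  set <- unique(set); universe <- unique(universe)
  ann <- annotations[annotations$protein_id %in% universe, , drop = FALSE]
  if (!"aspect" %in% names(ann)) ann$aspect <- NA_character_
  N <- length(universe); n <- length(set)

  per_term <- split(ann, ann$term_id)
  rows <- lapply(per_term, function(a) {
    members <- unique(a$protein_id)
    K <- length(members)
    if (K < min_universe) return(NULL)
    k <- sum(set %in% members)
    expected <- K / N * n
    p <- if (method == "hypergeometric") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
      if (any(tab < 0)) NA_real_ else
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(term_id = a$term_id[1L], aspect = a$aspect[1L],
               detected = k, expected = expected,
               ratio = k / expected, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term passes the universe-size floor")
  res$q <- bh_adjust(res$p)
  res <- res[order(res$p, -res$detected), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("term_enrichment", "data.frame")
  res
}
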