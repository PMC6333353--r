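# Physicochemical features of parental proteins and their per-dataset
# distributions.

#' GRAVY index (grand average of hydropathy)
#'
#' Arithmetic mean of per-residue Kyte-Doolittle hydropathy values. 'X'
#' residues are excluded from the mean.
#'
#' @param seq amino-acid sequence (one-letter code).
#' @return numeric in [-4.5, 4.5].
#' @export
gravy <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  aa <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  known <- aa %in% names(KD_SCALE)
  if (any(!known & aa != "X"))
    stop("non-standard residue(s): ", paste(unique(aa[!known & aa != "X"]),
                                            collapse = ", "))
  if (!any(known)) stop("sequence has no standard residues")
  mean(KD_SCALE[aa[known]])
}

# Net charge of a sequence at a given pH under the Henderson-Hasselbalch
# model; `counts` is the output of ionizable_counts().
net_charge <- function(ph, counts, pka) {
  pos <- c(nterm = 1, counts[c("K", "R", "H")])
  neg <- c(cterm = 1, counts[c("D", "E", "C", "Y")])
  qpos <- sum(pos / (1 + 10^(ph - pka[names(pos)])))
  qneg <- sum(neg / (1 + 10^(pka[names(neg)] - ph)))
  qpos - qneg
}

ionizable_counts <- function(seq) {
  aa <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  vapply(c("K", "R", "H", "D", "E", "C", "Y"),
         function(r) sum(aa == r), numeric(1))
}

#' Isoelectric point
#'
#' The pH at which the net charge of the peptide (Henderson-Hasselbalch sum
#' over the D, E, C, Y, H, K, R side chains plus the free termini) is zero.
#' The charge is strictly decreasing in pH, so the root is found by bisection
#' on [0, 14] to a tolerance of 0.002 pH units.
#'
#' @param seq amino-acid sequence.
#' @param pka a named pKa vector (see [PKA_TABLES]) or the name of a
#'   built-in table; default the Bjellqvist/ExPASy set.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = "bjellqvist") {
  if (is.character(pka) && length(pka) == 1L) {
    if (!pka %in% names(PKA_TABLES)) stop("unknown pKa table: ", pka)
    pka <- PKA_TABLES[[pka]]
  }
  counts <- ionizable_counts(seq)
  lo <- 0; hi <- 14
  while (hi - lo > 0.002) {
    mid <- (lo + hi) / 2
    if (net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Transmembrane residue fraction and membrane class
#'
#' Fraction of residues inside transmembrane spans, binned into four classes:
#' 0 -> `non-membrane`; (0, 10%) -> `peripheral`; [10%, 40%] ->
#' `intermediate`; >40% -> `integral`.
#'
#' @param length protein length in residues.
#' @param spans matrix or data.frame of TM spans with columns `start`, `end`
#'   (1-based inclusive); may have zero rows.
#' @param low,high class boundaries as fractions (defaults 0.10 and 0.40):
#'   the middle bin is closed, `[low, high]`.
#' @return list with `fraction` and `class`.
#' @export
tm_fraction <- function(length, spans, low = 0.10, high = 0.40) {
  if (is.null(spans) || NROW(spans) == 0L)
    return(list(fraction = 0, class = "non-membrane"))
  spans <- as.data.frame(spans)
  if (any(spans$start < 1 | spans$end > length | spans$start > spans$end))
    stop("TM span outside [1, length]")
  o <- order(spans$start)
  if (NROW(spans) > 1L &&
      any(spans$start[o][-1L] <= spans$end[o][-NROW(spans)]))
    stop("overlapping TM spans")
  frac <- sum(spans$end - spans$start + 1) / length
  list(fraction = frac, class = tm_class(frac, low, high))
}

tm_class <- function(frac, low = 0.10, high = 0.40) {
  ifelse(frac == 0, "non-membrane",
         ifelse(frac < low, "peripheral",
                ifelse(frac <= high, "intermediate", "integral")))
}

#' Feature table for every protein in a collection
#'
#' @param collection a `ligand_collection`.
#' @param pka pKa table name or vector for [isoelectric_point()].
#' @param tm_low,tm_high membrane-class boundaries (see [tm_fraction()]).
#' @return data.frame: `id`, `length`, `pI`, `gravy`, `tm_fraction`,
#'   `tm_class`, `has_signal`.
#' @export
protein_features <- function(collection, pka = "bjellqvist",
                             tm_low = 0.10, tm_high = 0.40) {
  prot <- collection$proteins
  tmspl <- split(collection$tm[c("start", "end")], collection$tm$protein_id)
  tmres <- lapply(prot$id, function(id) {
    tm_fraction(prot$length[match(id, prot$id)], tmspl[[id]],
                low = tm_low, high = tm_high)
  })
  data.frame(
    id = prot$id,
    length = prot$length,
    pI = vapply(prot$seq, isoelectric_point, numeric(1), pka = pka,
                USE.NAMES = FALSE),
    gravy = vapply(prot$seq, gravy, numeric(1), USE.NAMES = FALSE),
    tm_fraction = vapply(tmres, `[[`, numeric(1), "fraction"),
    tm_class = vapply(tmres, `[[`, character(1), "class"),
    has_signal = prot$id %in% collection$signal$protein_id,
    stringsAsFactors = FALSE)
}

#' Per-dataset feature distributions and tests against a control
#'
#' For the parental-protein set of each dataset: mean and SD of length, pI
#' and GRAVY; histogram counts on configurable bin edges; two-tailed
#' two-sample t-tests of each feature against the control dataset; and a
#' chi-square test of the membrane-class composition against the control's
#' proportions.
#'
#' @param collection a `ligand_collection`.
#' @param features output of [protein_features()] (computed if NULL).
#' @param control control dataset label (default `TAP+`).
#' @param t_mode `pooled` (classic Student) or `welch`.
#' @param bin_edges named list of numeric bin edges for `length`, `pI`,
#'   `gravy` histograms.
#' @return object of class `feature_distributions`: list with `summary`
#'   (per dataset x feature: n, mean, sd), `tests` (dataset vs control
#'   t-tests), `tm_tests` (chi-square on tm_class counts), `histograms`.
#' @export
feature_distributions <- function(collection, features = NULL,
                                  control = "TAP+", t_mode = "pooled",
                                  bin_edges = list(
                                    length = c(0, 200, 400, 600, 800, 1000,
                                               1500, 2000, 3000, Inf),
                                    pI = seq(2, 13, by = 1),
                                    gravy = seq(-2.5, 2.5, by = 0.5))) {
  if (is.null(features)) features <- protein_features(collection)
  labels <- sort(unique(collection$occurrences$dataset))
  if (!control %in% labels)
    stop("control dataset not present: ", control)
  feats <- c("length", "pI", "gravy")
  per <- lapply(labels, function(d) {
    features[features$id %in% parent_ids(collection, d), , drop = FALSE]
  })
  names(per) <- labels

  summ <- do.call(rbind, lapply(labels, function(d) {
    f <- per[[d]]
    data.frame(dataset = d, feature = feats, n = nrow(f),
               mean = vapply(feats, function(v) mean(f[[v]]), numeric(1)),
               sd = vapply(feats, function(v) stats::sd(f[[v]]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  hist_edges <- function(x, edges) {
    tab <- table(cut(x, breaks = edges, include.lowest = TRUE, right = TRUE))
    data.frame(bin = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  histograms <- do.call(rbind, lapply(labels, function(d) {
    do.call(rbind, lapply(feats, function(v) {
      h <- hist_edges(per[[d]][[v]], bin_edges[[v]])
      cbind(dataset = d, feature = v, h, stringsAsFactors = FALSE)
    }))
  }))

  others <- setdiff(labels, control)
  ctrl <- per[[control]]
  tests <- do.call(rbind, lapply(others, function(d) {
    f <- per[[d]]
    do.call(rbind, lapply(feats, function(v) {
      if (nrow(f) < 2L || nrow(ctrl) < 2L)
        return(data.frame(dataset = d, feature = v, t = NA_real_,
                          df = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      tt <- two_sample_t(f[[v]], ctrl[[v]], mode = t_mode)
      data.frame(dataset = d, feature = v, t = tt$statistic, df = tt$df,
                 p = tt$p, stringsAsFactors = FALSE)
    }))
  }))

  classes <- c("non-membrane", "peripheral", "intermediate", "integral")
  ctrl_tab <- table(factor(ctrl$tm_class, levels = classes))
  tm_tests <- do.call(rbind, lapply(others, function(d) {
    obs <- table(factor(per[[d]]$tm_class, levels = classes))
    expp <- as.numeric(ctrl_tab) / sum(ctrl_tab) * sum(obs)
    keep <- expp > 0
    if (sum(keep) < 2L || nrow(per[[d]]) < 2L)
      return(data.frame(dataset = d, chi2 = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    ct <- chi_square_gof(as.numeric(obs)[keep], expp[keep])
    data.frame(dataset = d, chi2 = ct$statistic, df = ct$df, p = ct$p,
               stringsAsFactors = FALSE)
  }))

  structure(list(summary = summ, tests = tests, tm_tests = tm_tests,
                 histograms = histograms, control = control),
            class = "feature_distributions")
}

#' @export
print.feature_distributions <- function(x, ...) {
  cat("Feature distributions (control:", x$control, ")\n")
  print(x$summary, digits = 4)
  if (!is.null(x$tests) && nrow(x$tests)) {
    cat("\nt-tests vs control:\n")
    print(x$tests, digits = 4)
  }
  invisible(x)
}
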