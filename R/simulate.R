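# Synthetic proteome/peptidome generator with planted, recoverable biases.
#
# The generator emulates the statistical structure of an immunopeptidomics
# study: several labeled peptide datasets drawn from one proteome, with
# configurable positional bias (terminal-decile "smile"), exact-terminal
# fractions, abundance-weighted parent sampling, cleavage-flank motifs and
# annotation-term plants. Planted biases are imposed by rejection sampling,
# never by editing sequences, so residue backgrounds stay honest.

sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) %% 97 + 1))
  as.integer((as.numeric(seed) %% 1048576 * 1009 + h) %% 2147483647)
}

#' Parameters for one synthetic peptide dataset
#'
#' @param n_peptides number of peptides to draw.
#' @param length_probs named numeric vector of peptide-length probabilities
#'   (names are lengths); default a class-I-like law over 8..14 centred on
#'   9-mers.
#' @param pi_exactC probability that a peptide ends exactly at its parent's
#'   C-terminus.
#' @param pi_exactN probability that a peptide starts at residue 1.
#' @param pi_term probability mass diverted to the terminal deciles
#'   (deciles 1-2 and 10), split `rho_N` : (1 - `rho_N`).
#' @param rho_N share of the terminal mass placed at the N-terminal deciles.
#' @param gamma abundance-sampling exponent: parent sampled with weight
#'   proportional to rpkm^gamma.
#' @param flank_motif NULL, or a list `list(cut, position, class, fold)`
#'   planting a residue-class enrichment at one flank position (e.g.
#'   `list(cut = "C", position = "P3", class = "AROMATIC", fold = 3)`),
#'   imposed by rejection sampling.
#' @param allele allele label written on the peptides.
#' @return list of dataset parameters.
#' @export
dataset_params <- function(n_peptides,
                           length_probs = c(`8` = 0.15, `9` = 0.45,
                                            `10` = 0.2, `11` = 0.1,
                                            `12` = 0.05, `13` = 0.03,
                                            `14` = 0.02),
                           pi_exactC = 0, pi_exactN = 0.002, pi_term = 0,
                           rho_N = 0.5, gamma = 0, flank_motif = NULL,
                           allele = "synthetic") {
  stopifnot(n_peptides >= 1, all(length_probs >= 0), sum(length_probs) > 0,
            pi_exactC >= 0, pi_exactN >= 0, pi_term >= 0,
            pi_exactC + pi_exactN + pi_term <= 1,
            rho_N >= 0, rho_N <= 1, gamma >= 0)
  if (!is.null(flank_motif)) {
    stopifnot(all(c("cut", "position", "class", "fold") %in%
                    names(flank_motif)),
              flank_motif$cut %in% c("N", "C"),
              flank_motif$position %in% FLANK_POSITIONS,
              flank_motif$fold >= 1)
  }
  list(n_peptides = n_peptides,
       length_probs = length_probs / sum(length_probs),
       pi_exactC = pi_exactC, pi_exactN = pi_exactN, pi_term = pi_term,
       rho_N = rho_N, gamma = gamma, flank_motif = flank_motif,
       allele = allele)
}

#' Simulation parameters
#'
#' @param n_proteins number of proteins in the synthetic proteome.
#' @param length_meanlog,length_sdlog log-normal law for protein length,
#'   truncated to `length_range`.
#' @param length_range allowed protein lengths (residues).
#' @param residue_freqs named 20-vector of residue frequencies (default a
#'   Swiss-Prot-like background).
#' @param rpkm_meanlog,rpkm_sdlog log-normal law for expression (RPKM).
#' @param p_membrane probability that a protein carries transmembrane
#'   helices (1-7 spans of 21 residues); 0 disables the track.
#' @param n_background_terms number of unplanted annotation terms.
#' @param term_plants list of `list(term, prevalence, fold, dataset)`
#'   entries: the term is present on proteins at `prevalence`, and parent
#'   sampling for `dataset` up-weights carriers by `fold`.
#' @param datasets named list of [dataset_params()] (names are dataset
#'   labels).
#' @param seed integer seed; one named pseudorandom stream is derived per
#'   sub-generator so adding a generator never perturbs the others.
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 1000,
                              length_meanlog = log(450),
                              length_sdlog = 0.8,
                              length_range = c(50, 5000),
                              residue_freqs = UNIPROT_FREQS,
                              rpkm_meanlog = 1, rpkm_sdlog = 1.5,
                              p_membrane = 0,
                              n_background_terms = 30,
                              term_plants = list(),
                              datasets = list(
                                `TAP+` = dataset_params(500)),
                              seed = 1L) {
  stopifnot(n_proteins >= 1, length_sdlog > 0, rpkm_sdlog > 0,
            length_range[1] >= 10, length_range[2] > length_range[1],
            p_membrane >= 0, p_membrane <= 1,
            abs(sum(residue_freqs) - 1) < 1e-6,
            length(datasets) >= 1, !is.null(names(datasets)))
  structure(list(n_proteins = n_proteins, length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog, length_range = length_range,
                 residue_freqs = residue_freqs,
                 rpkm_meanlog = rpkm_meanlog, rpkm_sdlog = rpkm_sdlog,
                 p_membrane = p_membrane,
                 n_background_terms = n_background_terms,
                 term_plants = term_plants, datasets = datasets,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' The `paperlike` preset
#'
#' Scenario defaults echoing the scale of a published TAP-independent
#' ligandome meta-analysis: four datasets (TAP+ 2125, TAP-C 428, TAP-NC
#' 623, HLA-II 2799 peptides), a 21% exact-C-terminal fraction in the
#' TAP-independent sets, a terminal-decile "smile" calibrated so TAP-C
#' places about 30% of peptides in the two N-terminal deciles and 35% in
#' the C-terminal decile, a stronger abundance-sampling exponent for TAP-C,
#' a C-cut P1' glycine motif on TAP-C, and one immune-response-like term
#' planted on HLA-II. These are scenario defaults, not reproductions of any
#' particular experiment.
#'
#' @param seed integer seed.
#' @param n_proteins proteome size (default 1500).
#' @return a `simulation_params` object.
#' @export
paperlike_params <- function(seed = 1L, n_proteins = 1500) {
  long_probs <- c(`13` = 0.25, `14` = 0.25, `15` = 0.2, `16` = 0.15,
                  `17` = 0.15)
  broad_probs <- c(`8` = 0.1, `9` = 0.2, `10` = 0.15, `11` = 0.15,
                   `12` = 0.15, `13` = 0.15, `14` = 0.1)
  simulation_params(
    n_proteins = n_proteins,
    p_membrane = 0.15,
    n_background_terms = 40,
    term_plants = list(list(term = "GO:0006955", prevalence = 0.05,
                            fold = 3, dataset = "HLA-II")),
    datasets = list(
      `TAP+` = dataset_params(2125, pi_exactC = 0.005, gamma = 0.3,
                              allele = "HLA-A2"),
      `TAP-C` = dataset_params(428, length_probs = broad_probs,
                               pi_exactC = 0.21, pi_term = 0.29,
                               rho_N = 0.69, gamma = 0.8,
                               flank_motif = list(cut = "C",
                                                  position = "P1'",
                                                  class = "GLY",
                                                  fold = 2.5),
                               allele = "HLA-B51"),
      `TAP-NC` = dataset_params(623, length_probs = broad_probs,
                                pi_exactC = 0.21, pi_term = 0.12,
                                rho_N = 0.55, gamma = 0.3,
                                allele = "HLA-E"),
      `HLA-II` = dataset_params(2799, length_probs = long_probs,
                                gamma = 0.3, allele = "HLA-DR")),
    seed = seed)
}

rtrunc_lnorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Simulate a proteome with expression and annotations
#'
#' Draws i.i.d. residue sequences with log-normal lengths, log-normal RPKM
#' values, optional transmembrane spans, and term annotations (background
#' pool plus planted terms). Deterministic under the params seed.
#'
#' @param params a `simulation_params` object.
#' @return list with `proteins` (id, seq), `expression` (protein_id, rpkm),
#'   `tm_annotations` (protein_id, track, start, end), `annotations`
#'   (protein_id, term_id, aspect).
#' @export
simulate_proteome <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  freqs <- params$residue_freqs
  n <- params$n_proteins
  ids <- sprintf("SYN%05d", seq_len(n))

  set.seed(sub_seed(params$seed, "lengths"))
  lens <- round(rtrunc_lnorm(n, params$length_meanlog, params$length_sdlog,
                             params$length_range))

  set.seed(sub_seed(params$seed, "sequences"))
  all_res <- sample(names(freqs), sum(lens), replace = TRUE, prob = freqs)
  seqs <- vapply(split(all_res, rep(seq_len(n), lens)), paste,
                 character(1), collapse = "")
  names(seqs) <- NULL

  set.seed(sub_seed(params$seed, "rpkm"))
  rpkm <- stats::rlnorm(n, params$rpkm_meanlog, params$rpkm_sdlog)

  tm <- data.frame(protein_id = character(), track = character(),
                   start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  if (params$p_membrane > 0) {
    set.seed(sub_seed(params$seed, "membrane"))
    is_mem <- stats::runif(n) < params$p_membrane
    spans <- lapply(which(is_mem), function(i) {
      k <- sample(1:7, 1L)
      # non-overlapping 21-residue helices separated by >= 5 residues
      span_len <- 21L; gap <- 5L
      need <- k * (span_len + gap)
      if (lens[i] < need) k <- max(1L, lens[i] %/% (span_len + gap))
      if (k < 1L) return(NULL)
      starts <- sort(sample(seq_len(lens[i] - span_len + 1L), k))
      keep <- c(TRUE, diff(starts) > span_len + gap)
      starts <- starts[keep]
      data.frame(protein_id = ids[i], track = "TM", start = starts,
                 end = starts + span_len - 1L, stringsAsFactors = FALSE)
    })
    spans <- spans[!vapply(spans, is.null, logical(1))]
    if (length(spans)) tm <- do.call(rbind, spans)
  }

  set.seed(sub_seed(params$seed, "terms"))
  ann <- list()
  if (params$n_background_terms > 0) {
    for (t in seq_len(params$n_background_terms)) {
      term <- sprintf("GO:9%06d", t)
      prev <- stats::runif(1, 0.01, 0.10)
      members <- ids[stats::runif(n) < prev]
      if (length(members))
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = members, term_id = term,
          aspect = sample(c("P", "C", "F"), 1L), stringsAsFactors = FALSE)
    }
  }
  for (pl in params$term_plants) {
    members <- ids[stats::runif(n) < pl$prevalence]
    if (length(members))
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = members, term_id = pl$term, aspect = "P",
        stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(protein_id = character(), term_id = character(),
               aspect = character(), stringsAsFactors = FALSE)
  rownames(annotations) <- NULL

  list(proteins = data.frame(id = ids, seq = seqs,
                             stringsAsFactors = FALSE),
       expression = data.frame(protein_id = ids, rpkm = rpkm,
                               stringsAsFactors = FALSE),
       tm_annotations = tm,
       annotations = annotations)
}

# Residue at a flank position for a candidate placement; NA when the
# position is undefined (outside the sequence or missing cut).
flank_residue_at <- function(seq, L, start, end, cut, position) {
  k <- match(position, FLANK_POSITIONS)
  idx <- if (cut == "N") {
    if (start == 1L) return(NA_character_)
    start - 4L + k
  } else {
    if (end == L) return(NA_character_)
    end - 3L + k
  }
  if (idx < 1L || idx > L) return(NA_character_)
  substr(seq, idx, idx)
}

#' Simulate one peptide dataset from a proteome
#'
#' Parents are sampled with weight proportional to rpkm^gamma (times any
#' term-plant boost for this dataset); peptide placement follows the
#' positional parameters; a flank motif, when requested, is imposed by
#' rejection sampling with the out-of-class acceptance probability chosen
#' to realize the requested fold over the proteome background.
#'
#' @param proteome output of [simulate_proteome()].
#' @param dparams a [dataset_params()] list.
#' @param label dataset label.
#' @param params the enclosing `simulation_params` (for residue background,
#'   term plants and the seed).
#' @return data.frame of peptide rows: `peptide`, `protein_id`, `start`,
#'   `end`, `dataset`, `allele`.
#' @export
simulate_peptidome <- function(proteome, dparams, label, params) {
  prot <- proteome$proteins
  lens <- nchar(prot$seq)
  rpkm <- proteome$expression$rpkm[match(prot$id,
                                         proteome$expression$protein_id)]
  w <- rpkm^dparams$gamma
  for (pl in params$term_plants) {
    if (!identical(pl$dataset, label)) next
    carriers <- prot$id %in%
      proteome$annotations$protein_id[proteome$annotations$term_id ==
                                        pl$term]
    w[carriers] <- w[carriers] * pl$fold
  }
  w <- w / sum(w)

  motif <- dparams$flank_motif
  b_out <- 1
  if (!is.null(motif)) {
    cls <- if (length(motif$class) == 1L &&
               motif$class %in% names(RESIDUE_CLASSES))
      RESIDUE_CLASSES[[motif$class]] else motif$class
    q <- sum(params$residue_freqs[cls])
    if (motif$fold * q >= 1)
      stop("unattainable flank motif: fold ", motif$fold,
           " x background ", signif(q, 3), " >= 1")
    b_out <- (1 - motif$fold * q) / (motif$fold * (1 - q))
    motif$members <- cls
  }

  plens <- as.integer(names(dparams$length_probs))
  set.seed(sub_seed(params$seed, paste0("peptidome_", label)))
  n <- dparams$n_peptides
  # average acceptance probability of a background site; used for
  # placements whose motif position is undefined so they are neither
  # favored nor penalized relative to defined sites
  p_accept_bg <- if (is.null(motif)) 1 else
    sum(params$residue_freqs[motif$members]) +
    (1 - sum(params$residue_freqs[motif$members])) * b_out

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    # placement type is drawn ONCE, so motif rejection (which re-draws the
    # site) cannot shift the exact-terminal / terminal-decile fractions
    u <- stats::runif(1)
    type <- if (u < dparams$pi_exactC) "exactC"
            else if (u < dparams$pi_exactC + dparams$pi_exactN) "exactN"
            else if (u < dparams$pi_exactC + dparams$pi_exactN +
                     dparams$pi_term) "term"
            else "uniform"
    for (attempt in seq_len(1000L)) {
      pi_idx <- sample.int(nrow(prot), 1L, prob = w)
      L <- lens[pi_idx]
      len <- plens[sample.int(length(plens), 1L,
                              prob = dparams$length_probs)]
      if (type == "exactC") {
        start <- L - len + 1L; end <- L
      } else if (type == "exactN") {
        start <- 1L; end <- len
      } else if (type == "term") {
        # midpoint in deciles 1-2 (N) or decile 10 (C), clamped away from
        # the exact termini so the exact fractions stay parameter-driven
        m <- if (stats::runif(1) < dparams$rho_N)
          stats::runif(1, 1, 0.2 * L) else stats::runif(1, 0.9 * L, L)
        start <- round(m - (len - 1) / 2)
        start <- min(max(start, 2L), L - len)
        end <- start + len - 1L
      } else {
        start <- sample(2:(L - len), 1L)
        end <- start + len - 1L
      }
      if (is.null(motif)) break
      r <- flank_residue_at(prot$seq[pi_idx], L, start, end, motif$cut,
                            motif$position)
      if (is.na(r)) {
        if (stats::runif(1) < p_accept_bg) break
      } else if (r %in% motif$members) {
        break
      } else if (stats::runif(1) < b_out) {
        break
      }
    }
    rows[[i]] <- list(pi_idx, start, end)
  }
  idx <- vapply(rows, `[[`, numeric(1), 1L)
  start <- vapply(rows, `[[`, numeric(1), 2L)
  end <- vapply(rows, `[[`, numeric(1), 3L)
  data.frame(peptide = substr(prot$seq[idx], start, end),
             protein_id = prot$id[idx],
             start = as.integer(start), end = as.integer(end),
             dataset = label, allele = dparams$allele,
             stringsAsFactors = FALSE)
}

#' Simulate a full study: proteome plus all peptide datasets
#'
#' Runs [simulate_proteome()] and [simulate_peptidome()] for every dataset
#' in the params and, optionally, writes the standard input files
#' (proteome.fasta, peptides.tsv, expression.tsv, annotations.tsv,
#' annotations.gaf) plus truth.json recording every planted parameter.
#'
#' @param params a `simulation_params` (e.g. [paperlike_params()]).
#' @param out_dir optional output directory.
#' @return list with `proteins`, `expression`, `tm_annotations`,
#'   `annotations`, `peptides` and `truth` (the planted parameters).
#' @export
simulate_ligandome <- function(params, out_dir = NULL) {
  proteome <- simulate_proteome(params)
  peptides <- do.call(rbind, lapply(names(params$datasets), function(d) {
    simulate_peptidome(proteome, params$datasets[[d]], d, params)
  }))
  rownames(peptides) <- NULL
  truth <- list(
    seed = params$seed,
    n_proteins = params$n_proteins,
    datasets = lapply(params$datasets, function(dp)
      dp[c("n_peptides", "pi_exactC", "pi_exactN", "pi_term", "rho_N",
           "gamma", "flank_motif")]),
    term_plants = params$term_plants)
  out <- c(proteome, list(peptides = peptides, truth = truth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_proteome(out$proteins, file.path(out_dir, "proteome.fasta"))
    write_tsv(peptides, file.path(out_dir, "peptides.tsv"))
    write_tsv(out$expression, file.path(out_dir, "expression.tsv"))
    if (nrow(out$tm_annotations))
      write_tsv(out$tm_annotations, file.path(out_dir, "annotations.tsv"))
    write_gaf(out$annotations, file.path(out_dir, "annotations.gaf"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  out
}

#' Write annotations as a minimal GAF 2.2 file
#' @param annotations data.frame `protein_id`, `term_id`, `aspect`.
#' @param path output path.
#' @export
write_gaf <- function(annotations, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  if (nrow(annotations)) {
    lines <- paste("SYNDB", annotations$protein_id, annotations$protein_id,
                   "", annotations$term_id, "SYN:0000001", "IEA", "",
                   annotations$aspect, "", "", "protein", "taxon:9606",
                   "20260101", "SYNDB", "", "", sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
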