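# Readers/writers and the ligand collection container.

#' Read a proteome from FASTA
#'
#' Parses protein sequences, takes the first whitespace-delimited token of
#' each header as the identifier, uppercases sequences and strips a single
#' trailing '*' (stop). Records with the same id and identical sequence are
#' collapsed to one; the same id with differing sequences is an error.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id` and `seq`, one row per unique id.
#' @export
read_proteome <- function(path) {
  stopifnot(file.exists(path))
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*$", "", seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  key <- paste(ids, seqs)
  keep <- !duplicated(key)
  ids <- ids[keep]; seqs <- seqs[keep]
  if (anyDuplicated(ids))
    stop("duplicate id(s) with differing sequences: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad))
    stop("non-residue characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  res <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  nonstd <- grepl("X", res$seq, fixed = TRUE)
  if (any(nonstd))
    message(sum(nonstd), " sequence(s) contain 'X' (unknown residue)")
  rownames(res) <- NULL
  res
}

#' Write proteins to FASTA
#' @param proteins data.frame with `id`, `seq`.
#' @param path output path.
#' @export
write_proteome <- function(proteins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", proteins$id, "\n", proteins$seq), con)
  invisible(path)
}

#' Locate a peptide within a protein sequence
#'
#' Finds all exact (possibly overlapping) occurrences of `peptide_seq`
#' in `protein_seq`.
#'
#' @param peptide_seq non-empty peptide sequence.
#' @param protein_seq parent protein sequence.
#' @return matrix with columns `start`, `end` (1-based inclusive), ordered
#'   by ascending start; zero rows when the peptide does not occur.
#' @export
locate_peptide <- function(peptide_seq, protein_seq) {
  stopifnot(nchar(peptide_seq) >= 1L)
  m <- Biostrings::matchPattern(peptide_seq, Biostrings::AAString(protein_seq))
  cbind(start = Biostrings::start(m), end = Biostrings::end(m))
}

#' Collapse byte-identical protein sequences
#'
#' Proteins with identical sequences are merged under the lexicographically
#' smallest id; an alias map records every merged id.
#'
#' @param proteins data.frame with `id`, `seq`.
#' @return list with `proteins` (deduplicated) and `alias` (named character
#'   vector mapping every original id to its canonical id).
#' @export
deduplicate_proteins <- function(proteins) {
  canon <- vapply(split(proteins$id, proteins$seq),
                  function(ids) sort(ids)[1L], character(1))
  alias <- canon[proteins$seq]
  names(alias) <- proteins$id
  keep <- proteins[proteins$id == alias, , drop = FALSE]
  keep <- keep[order(keep$id), , drop = FALSE]
  rownames(keep) <- NULL
  list(proteins = keep, alias = alias)
}

#' Read a peptide table
#'
#' Tab-delimited with a header; required columns `peptide`, `protein_id`,
#' `dataset`; optional `allele`, `start`, `end`.
#' @param path path to TSV.
#' @return data.frame of peptide rows.
#' @export
read_peptides <- function(path) {
  pep <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("peptide", "protein_id", "dataset")
  miss <- setdiff(need, names(pep))
  if (length(miss))
    stop("peptide table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"allele" %in% names(pep)) pep$allele <- NA_character_
  pep$peptide <- toupper(pep$peptide)
  pep
}

#' Read an expression table (protein_id, rpkm)
#' @param path path to TSV with columns `protein_id` and `rpkm`.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  ex <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "rpkm") %in% names(ex)))
  if (any(ex$rpkm < 0, na.rm = TRUE)) stop("negative RPKM values")
  ex
}

#' Read a transmembrane/signal annotation table
#'
#' TSV columns: `protein_id`, `track` (TM or SIGNAL), `start`, `end`
#' (1-based inclusive).
#' @param path path to TSV.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  an <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "track", "start", "end") %in% names(an)))
  bad <- !an$track %in% c("TM", "SIGNAL")
  if (any(bad)) stop("unknown annotation track(s): ",
                     paste(unique(an$track[bad]), collapse = ", "))
  an
}

#' Read GO annotations from a GAF 2.x file
#'
#' Uses columns 2 (object id), 5 (GO id) and 9 (aspect); comment lines
#' starting with '!' are skipped; duplicate (protein, term) pairs collapse.
#' @param path path to GAF file.
#' @return data.frame with `protein_id`, `term_id`, `aspect`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(), term_id = character(),
                      aspect = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L)) stop("malformed GAF line (fewer than 9 columns)")
  ann <- data.frame(
    protein_id = vapply(parts, `[[`, "", 2L),
    term_id    = vapply(parts, `[[`, "", 5L),
    aspect     = vapply(parts, `[[`, "", 9L),
    stringsAsFactors = FALSE)
  ann[!duplicated(ann[c("protein_id", "term_id")]), , drop = FALSE]
}

#' Assemble a ligand collection
#'
#' Places every peptide on its stated parent, verifies coordinates,
#' fractionally weights multi-occurrence peptides (weight 1/k over the k
#' exact matches) and drops unplaceable peptides with a warning.
#'
#' @param proteins data.frame with `id`, `seq` (from [read_proteome()]).
#' @param peptides data.frame with `peptide`, `protein_id`, `dataset`,
#'   optional `allele`, `start`, `end`. When coordinates are given they are
#'   verified against the sequence; on mismatch the peptide is re-located.
#' @param expression optional data.frame `protein_id`, `rpkm`.
#' @param annotations optional data.frame `protein_id`, `track`, `start`, `end`.
#' @return an object of class `ligand_collection`: a list with `proteins`
#'   (id, seq, length, rpkm), `tm` and `signal` span tables, `occurrences`
#'   (peptide, protein_id, start, end, dataset, allele, weight) and
#'   `dataset_sizes` (weighted peptide counts per label). Rejected peptides
#'   are kept in attribute `rejected`.
#' @export
build_collection <- function(proteins, peptides, expression = NULL,
                             annotations = NULL) {
  stopifnot(is.data.frame(proteins), all(c("id", "seq") %in% names(proteins)))
  if (anyDuplicated(proteins$id)) stop("duplicate protein ids")
  seqs <- stats::setNames(proteins$seq, proteins$id)
  lens <- nchar(seqs)

  if (!"allele" %in% names(peptides)) peptides$allele <- NA_character_
  has_coord <- all(c("start", "end") %in% names(peptides))

  known <- !is.na(peptides$protein_id) & peptides$protein_id %in% names(seqs)
  pseq <- rep(NA_character_, nrow(peptides))
  pseq[known] <- unname(seqs[peptides$protein_id[known]])
  # fast path: stated coordinates verified against the sequence in bulk
  verified <- rep(FALSE, nrow(peptides))
  if (has_coord) {
    ok <- known & !is.na(peptides$start) & !is.na(peptides$end) &
      peptides$start >= 1 & peptides$end <= nchar(pseq) &
      !is.na(peptides$start <= peptides$end) & peptides$start <= peptides$end
    ok[is.na(ok)] <- FALSE
    verified <- ok
    verified[ok] <- substr(pseq[ok], peptides$start[ok],
                           peptides$end[ok]) == peptides$peptide[ok]
  }
  fast <- if (any(verified)) data.frame(
    peptide = peptides$peptide[verified],
    protein_id = peptides$protein_id[verified],
    start = as.integer(peptides$start[verified]),
    end = as.integer(peptides$end[verified]),
    dataset = peptides$dataset[verified],
    allele = peptides$allele[verified],
    weight = 1, stringsAsFactors = FALSE) else NULL

  # slow path: locate by exact-substring search (all occurrences, 1/k each)
  todo <- which(!verified)
  out <- vector("list", length(todo))
  rejected <- logical(length(todo))
  for (j in seq_along(todo)) {
    i <- todo[j]
    if (!known[i]) {
      rejected[j] <- TRUE
      next
    }
    hits <- locate_peptide(peptides$peptide[i], pseq[i])
    if (nrow(hits) == 0L) {
      rejected[j] <- TRUE
      next
    }
    out[[j]] <- data.frame(
      peptide = peptides$peptide[i], protein_id = peptides$protein_id[i],
      start = as.integer(hits[, "start"]), end = as.integer(hits[, "end"]),
      dataset = peptides$dataset[i], allele = peptides$allele[i],
      weight = 1 / nrow(hits), stringsAsFactors = FALSE)
  }
  if (any(rejected))
    warning(sum(rejected), " peptide(s) could not be placed on their parent ",
            "and were dropped")
  occ <- do.call(rbind, c(list(fast), out[!vapply(out, is.null,
                                                  logical(1))]))
  if (is.null(occ))
    occ <- data.frame(peptide = character(), protein_id = character(),
                      start = integer(), end = integer(),
                      dataset = character(), allele = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  rownames(occ) <- NULL
  rejected_rows <- peptides[todo[rejected], , drop = FALSE]

  prot <- data.frame(id = proteins$id, seq = unname(seqs),
                     length = unname(lens), rpkm = NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    idx <- match(prot$id, expression$protein_id)
    prot$rpkm <- expression$rpkm[idx]
  }
  tm <- signal <- data.frame(protein_id = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    ann <- annotations[annotations$protein_id %in% prot$id, , drop = FALSE]
    validate_spans(ann, stats::setNames(prot$length, prot$id))
    tm <- ann[ann$track == "TM", c("protein_id", "start", "end"), drop = FALSE]
    signal <- ann[ann$track == "SIGNAL", c("protein_id", "start", "end"),
                  drop = FALSE]
    rownames(tm) <- rownames(signal) <- NULL
  }

  sizes <- if (nrow(occ)) vapply(split(occ$weight, occ$dataset), sum,
                                 numeric(1)) else numeric(0)
  structure(
    list(proteins = prot, tm = tm, signal = signal,
         occurrences = occ, dataset_sizes = sizes),
    rejected = rejected_rows,
    class = "ligand_collection")
}

validate_spans <- function(ann, lens) {
  if (!nrow(ann)) return(invisible(TRUE))
  L <- lens[ann$protein_id]
  if (any(ann$start < 1 | ann$end > L | ann$start > ann$end))
    stop("annotation span outside sequence bounds")
  # overlap check within a (protein, track)
  by <- split(ann, paste(ann$protein_id, ann$track))
  for (g in by) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("overlapping spans on track ", g$track[1L],
           " of protein ", g$protein_id[1L])
  }
  invisible(TRUE)
}

#' @export
print.ligand_collection <- function(x, ...) {
  cat("ligand_collection:", nrow(x$proteins), "proteins,",
      nrow(x$occurrences), "peptide occurrences\n")
  if (length(x$dataset_sizes)) {
    cat("datasets (weighted peptide counts):\n")
    for (d in names(x$dataset_sizes))
      cat(sprintf("  %-8s %.1f\n", d, x$dataset_sizes[[d]]))
  }
  invisible(x)
}

#' Parental proteins of a dataset
#'
#' @param collection a `ligand_collection`.
#' @param dataset a dataset label, or NULL for all parents.
#' @return character vector of protein ids with at least one placed peptide.
#' @export
parent_ids <- function(collection, dataset = NULL) {
  occ <- collection$occurrences
  if (!is.null(dataset)) {
    if (!dataset %in% occ$dataset) stop("unknown dataset: ", dataset)
    occ <- occ[occ$dataset == dataset, , drop = FALSE]
  }
  sort(unique(occ$protein_id))
}

#' Overlap of parental-protein sets between datasets
#'
#' Computes Venn-cell counts (proteins whose dataset membership is exactly a
#' given label subset) and pairwise shared-protein percentages.
#'
#' @param collection a `ligand_collection` with at least two dataset labels.
#' @return list with `venn` (data.frame: `datasets` label-subset string,
#'   `count`) and `pairwise` (data.frame: `set_a`, `set_b`, `shared`,
#'   `pct_of_a` = 100 * shared / |set_a|).
#' @export
dataset_overlap <- function(collection) {
  occ <- collection$occurrences
  labels <- sort(unique(occ$dataset))
  if (length(labels) < 2L) stop("need at least two dataset labels")
  membership <- lapply(split(occ$dataset, occ$protein_id),
                       function(d) sort(unique(d)))
  cell <- vapply(membership, paste, "", collapse = "&")
  venn <- as.data.frame(table(cell), stringsAsFactors = FALSE)
  names(venn) <- c("datasets", "count")
  venn <- venn[order(-venn$count, venn$datasets), , drop = FALSE]
  rownames(venn) <- NULL

  sets <- lapply(labels, function(d) parent_ids(collection, d))
  names(sets) <- labels
  pw <- expand.grid(set_a = labels, set_b = labels,
                    stringsAsFactors = FALSE)
  pw <- pw[pw$set_a != pw$set_b, , drop = FALSE]
  pw$shared <- mapply(function(a, b) length(intersect(sets[[a]], sets[[b]])),
                      pw$set_a, pw$set_b)
  pw$pct_of_a <- 100 * pw$shared / lengths(sets)[pw$set_a]
  rownames(pw) <- NULL
  list(venn = venn, pairwise = pw)
}

#' Write a data.frame as TSV (UTF-8, '.' decimal, header row)
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
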