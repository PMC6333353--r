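# Small in-code fixtures shared across test files.

# A toy collection: proteins given as a named character vector of
# sequences; peptides as (peptide, protein_id, dataset[, allele]).
toy_collection <- function(seqs, peptides, ...) {
  proteins <- data.frame(id = names(seqs), seq = unname(seqs),
                         stringsAsFactors = FALSE)
  suppressWarnings(build_collection(proteins, peptides, ...))
}

random_protein <- function(len, freqs = NULL) {
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  paste(sample(AA_ALPHABET, len, replace = TRUE, prob = freqs),
        collapse = "")
}

write_temp_fasta <- function(headers, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# Independent charge model for the pI grid-scan oracle (same physics,
# different search: 0.001-step scan for the sign change).
grid_scan_pi <- function(seq, pka = PKA_TABLES$bjellqvist) {
  aa <- strsplit(seq, "")[[1]]
  cnt <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                function(r) sum(aa == r), numeric(1))
  charge <- function(ph) {
    pos <- c(nterm = 1, cnt[c("K", "R", "H")])
    neg <- c(cterm = 1, cnt[c("D", "E", "C", "Y")])
    sum(pos / (1 + 10^(ph - pka[names(pos)]))) -
      sum(neg / (1 + 10^(pka[names(neg)] - ph)))
  }
  grid <- seq(0, 14, by = 0.001)
  q <- vapply(grid, charge, numeric(1))
  i <- which(q <= 0)[1]
  (grid[i - 1] + grid[i]) / 2
}
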