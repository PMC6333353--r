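small_params <- function(seed = 1, ...) {
  simulation_params(n_proteins = 120, datasets = list(
    D = dataset_params(200, ...)), seed = seed)
}

test_that("the generator is byte-deterministic under a fixed seed", {
  p <- paperlike_params(seed = 5, n_proteins = 60)
  p$datasets <- lapply(p$datasets, function(d) { d$n_peptides <- 30; d })
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_ligandome(p, out_dir = d1)
  simulate_ligandome(p, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the proteome
  p2 <- paperlike_params(seed = 6, n_proteins = 60)
  s2 <- simulate_proteome(p2)
  s1 <- simulate_proteome(p)
  expect_false(identical(s1$proteins$seq, s2$proteins$seq))
})

test_that("proteome composition and length law match their parameters", {
  freqs <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  p <- simulation_params(n_proteins = 1000, residue_freqs = freqs,
                         length_meanlog = log(600) - 0.8^2 / 2,
                         length_sdlog = 0.8,
                         datasets = list(D = dataset_params(10)),
                         seed = 3)
  prot <- simulate_proteome(p)
  comp <- compute_background(prot$proteins$seq)
  expect_true(all(abs(comp - 0.05) < 0.002))
  expect_equal(mean(nchar(prot$proteins$seq)), 600, tolerance = 0.05)
  expect_true(all(nchar(prot$proteins$seq) >= 50))
  expect_true(all(prot$expression$rpkm > 0))
})

test_that("every emitted peptide is an exact substring at its coordinates", {
  sim <- simulate_ligandome(small_params(seed = 4, pi_exactC = 0.2,
                                         pi_term = 0.3, gamma = 0.5))
  seqs <- stats::setNames(sim$proteins$seq, sim$proteins$id)
  parents <- seqs[sim$peptides$protein_id]
  expect_equal(substr(parents, sim$peptides$start, sim$peptides$end),
               unname(sim$peptides$peptide), ignore_attr = TRUE)
  expect_equal(nchar(sim$peptides$peptide),
               sim$peptides$end - sim$peptides$start + 1L)
})

test_that("the null configuration shows no positional or abundance bias", {
  p <- simulation_params(n_proteins = 150,
                         length_meanlog = log(1500), length_sdlog = 0.3,
                         datasets = list(D = dataset_params(5000)),
                         seed = 8)
  sim <- simulate_ligandome(p)
  col <- build_collection(sim$proteins, sim$peptides, sim$expression)
  pr <- positional_profile(col, "D")
  ut <- decile_uniformity_test(pr)
  expect_gt(ut$p, 0.001)
  expect_lt(pr$n_exact_C / pr$n_total, 0.01)
  # no rpkm-peptide-count correlation at gamma = 0
  cnt <- table(factor(sim$peptides$protein_id, levels = sim$proteins$id))
  rho <- stats::cor(sim$expression$rpkm, as.numeric(cnt),
                    method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("planted exact-C fraction is recovered", {
  sim <- simulate_ligandome(small_params(seed = 9, pi_exactC = 0.21),
                            out_dir = NULL)
  col <- build_collection(sim$proteins, sim$peptides)
  pr <- positional_profile(col, "D")
  est <- pr$n_exact_C / pr$n_total
  expect_gt(est, 0.15)
  expect_lt(est, 0.27)
  expect_equal(sim$truth$datasets$D$pi_exactC, 0.21)
})

test_that("a planted flank motif realizes close to its target fold", {
  p <- simulation_params(
    n_proteins = 150,
    datasets = list(D = dataset_params(
      600, flank_motif = list(cut = "C", position = "P3",
                              class = "AROMATIC", fold = 3))),
    seed = 10)
  sim <- simulate_ligandome(p)
  col <- build_collection(sim$proteins, sim$peptides)
  en <- flank_enrichment(flank_counts(col, "D"))
  got <- en[en$cut == "C" & en$position == "P3" & en$unit == "AROMATIC", ]
  expect_gt(got$ratio, 2.4)
  expect_lt(got$ratio, 3.6)
  expect_true(got$significant)
})

test_that("unattainable motif folds are rejected with a diagnostic", {
  p <- simulation_params(
    n_proteins = 20,
    datasets = list(D = dataset_params(
      10, flank_motif = list(cut = "C", position = "P1",
                             class = "ALIPHATIC", fold = 5))),
    seed = 11)
  expect_error(simulate_ligandome(p), "unattainable")
})

test_that("generator outputs are valid inputs for every reader", {
  dir <- withr::local_tempdir()
  p <- paperlike_params(seed = 12, n_proteins = 80)
  p$datasets <- lapply(p$datasets, function(d) { d$n_peptides <- 40; d })
  simulate_ligandome(p, out_dir = dir)
  prot <- read_proteome(file.path(dir, "proteome.fasta"))
  expect_equal(nrow(prot), 80)
  pep <- read_peptides(file.path(dir, "peptides.tsv"))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  ann <- read_annotations(file.path(dir, "annotations.tsv"))
  gaf <- read_gaf(file.path(dir, "annotations.gaf"))
  expect_true(all(c("protein_id", "term_id", "aspect") %in% names(gaf)))
  col <- build_collection(prot, pep, expr, ann)
  expect_equal(nrow(col$occurrences), 160)
  expect_equal(nrow(attr(col, "rejected")), 0)
})
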