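make_expr_collection <- function(n = 40, seed = 61) {
  set.seed(seed)
  seqs <- stats::setNames(replicate(n, random_protein(80)),
                          sprintf("P%03d", seq_len(n)))
  list(seqs = seqs)
}

test_that("abundance_representation computes strata and folds", {
  # dataset parents: 50% above threshold; reference proteome: 25%
  seqs <- stats::setNames(replicate(8, random_protein(60)),
                          sprintf("P%d", 1:8))
  expr <- data.frame(protein_id = names(seqs),
                     rpkm = c(20, 20, 1, 1, 1, 1, 1, 1))
  peps <- data.frame(peptide = substr(unlist(seqs[1:4]), 5, 13),
                     protein_id = names(seqs)[1:4], dataset = "D",
                     stringsAsFactors = FALSE)
  col <- toy_collection(seqs, peps, expression = expr)
  ab <- abundance_representation(col, threshold = 8)
  expect_equal(ab$folds$fold_protein, 2)
  # strata fractions sum to 1 per dataset (including unmeasured)
  s <- ab$strata
  expect_equal(sum(s$protein_fraction), 1)
  expect_equal(sum(s$peptide_fraction), 1)
})

test_that("unmeasured proteins form their own stratum, excluded from folds", {
  seqs <- stats::setNames(replicate(4, random_protein(60)),
                          sprintf("P%d", 1:4))
  expr <- data.frame(protein_id = c("P1", "P2"), rpkm = c(20, 1))
  peps <- data.frame(peptide = substr(unlist(seqs), 5, 13),
                     protein_id = names(seqs), dataset = "D",
                     stringsAsFactors = FALSE)
  ab <- abundance_representation(toy_collection(seqs, peps,
                                                expression = expr))
  s <- ab$strata
  expect_equal(s$protein_count[s$bin == "unmeasured"], 2)
  expect_equal(ab$folds$n_measured, 2)
})

test_that("dataset association follows containment and the 2x ratio rule", {
  seqs <- c(PA = strrep("ACDEFGHIKL", 8), PB = strrep("MNPQRSTVWY", 8),
            PC = strrep("LKIHGFEDCA", 8))
  mkpep <- function(pid, d, n, off = 0) do.call(rbind, lapply(seq_len(n),
    function(i) data.frame(peptide = substr(seqs[[pid]], 2 + i + off,
                                            10 + i + off),
                           protein_id = pid, dataset = d,
                           stringsAsFactors = FALSE)))
  # PA: 4 peptides TAP-C + 4 TAP+; PB only TAP-C; PC mostly in a small set
  peps <- rbind(mkpep("PA", "TAP-C", 4), mkpep("PA", "TAP+", 4, off = 10),
                mkpep("PB", "TAP-C", 4, off = 30),
                mkpep("PC", "TAP-C", 7, off = 40),
                mkpep("PC", "TAP+", 1, off = 60))
  col <- toy_collection(seqs, peps)

  # study-scale dataset sizes (sum 3176, TAP-C share 0.331)
  col$dataset_sizes <- c(`TAP-C` = 1051, `TAP+` = 2125)
  assoc <- assign_exclusive_datasets(col)
  pa <- assoc[assoc$protein_id == "PA" & assoc$dataset == "TAP-C", ]
  expect_equal(pa$ratio, (4 / 8) / (1051 / 3176), tolerance = 1e-12)
  expect_equal(round(pa$ratio, 2), 1.51)
  expect_false(pa$associated)
  # strict containment always associates
  pb <- assoc[assoc$protein_id == "PB" & assoc$dataset == "TAP-C", ]
  expect_true(pb$strictly_contained)
  expect_true(pb$associated)

  # 7 of 8 peptides in a dataset holding 10% of all peptides
  col$dataset_sizes <- c(`TAP-C` = 100, `TAP+` = 900)
  assoc2 <- assign_exclusive_datasets(col)
  pc <- assoc2[assoc2$protein_id == "PC" & assoc2$dataset == "TAP-C", ]
  expect_equal(pc$ratio, (7 / 8) / 0.1)
  expect_true(pc$associated)
})

test_that("strict containment can never be vetoed by the ratio rule", {
  set.seed(62)
  seqs <- stats::setNames(replicate(15, random_protein(70)),
                          sprintf("P%02d", 1:15))
  peps <- do.call(rbind, lapply(names(seqs), function(pid) {
    d <- sample(c("A", "B", "C"), 1)
    k <- sample(1:3, 1)
    s <- sample(2:50, k)
    data.frame(peptide = substr(seqs[[pid]], s, s + 8), protein_id = pid,
               dataset = d, stringsAsFactors = FALSE)
  }))
  assoc <- assign_exclusive_datasets(toy_collection(seqs, peps))
  expect_true(all(assoc$associated[assoc$strictly_contained]))
})

test_that("term_enrichment arithmetic and orderings are correct", {
  universe <- sprintf("U%04d", 1:1000)
  # term on 10/1000 universe proteins; set of 100 contains 5 of them
  ann <- data.frame(protein_id = universe[1:10], term_id = "GO:0000001",
                    aspect = "P", stringsAsFactors = FALSE)
  set <- c(universe[1:5], universe[101:195])
  te <- term_enrichment(set, ann, universe)
  expect_equal(te$expected, 1)
  expect_equal(te$ratio, 5)
  expect_equal(te$detected, 5)
  expect_lt(te$p, 0.01)
  th <- term_enrichment(set, ann, universe, method = "hypergeometric")
  expect_equal(th$p, stats::phyper(4, 10, 990, 100, lower.tail = FALSE))
  expect_error(term_enrichment(set, ann[0, ], universe), "empty")
  expect_error(term_enrichment("NOT_IN_UNIVERSE", ann, universe),
               "contained")
})

test_that("chi-square and hypergeometric p-values agree in direction", {
  set.seed(63)
  universe <- sprintf("U%03d", 1:200)
  agree <- 0L; total <- 0L
  for (i in 1:100) {
    members <- sample(universe, sample(10:60, 1))
    ann <- data.frame(protein_id = members, term_id = "GO:0000007",
                      aspect = "P", stringsAsFactors = FALSE)
    set <- sample(universe, 50)
    tc <- term_enrichment(set, ann, universe, method = "chi2")
    th <- term_enrichment(set, ann, universe, method = "hypergeometric")
    total <- total + 1L
    # enriched sets should look enriched (small p) under both tests
    if ((tc$p < 0.05) == (th$p < 0.05) || tc$ratio < 1) agree <- agree + 1L
  }
  expect_gte(agree / total, 0.9)
})

test_that("random sets yield no BH-significant terms", {
  set.seed(64)
  universe <- sprintf("U%03d", 1:300)
  ann <- do.call(rbind, lapply(1:20, function(t) {
    data.frame(protein_id = sample(universe, 30),
               term_id = sprintf("GO:%07d", t), aspect = "P",
               stringsAsFactors = FALSE)
  }))
  # exact (hypergeometric) p-values: essentially no BH discoveries
  n_sig <- vapply(1:20, function(i) {
    te <- term_enrichment(sample(universe, 40), ann, universe,
                          method = "hypergeometric")
    sum(te$q < 0.05)
  }, numeric(1))
  expect_lte(mean(n_sig), 0.2)
  # the chi-square approximation is slightly anti-conservative at small
  # expected counts but must stay near the null too
  n_sig2 <- vapply(1:20, function(i) {
    te <- term_enrichment(sample(universe, 40), ann, universe)
    sum(te$q < 0.05)
  }, numeric(1))
  expect_lte(mean(n_sig2), 0.5)
})

test_that("a planted term ranks first by p-value", {
  set.seed(65)
  universe <- sprintf("U%04d", 1:1000)
  ann_bg <- do.call(rbind, lapply(1:15, function(t) {
    data.frame(protein_id = sample(universe, 60),
               term_id = sprintf("GO:%07d", t), aspect = "P",
               stringsAsFactors = FALSE)
  }))
  planted <- "GO:0006955"
  carriers <- sample(universe, 80)
  ann <- rbind(ann_bg, data.frame(protein_id = carriers,
                                  term_id = planted, aspect = "P",
                                  stringsAsFactors = FALSE))
  hits <- 0L
  for (i in 1:10) {
    # set of 200 with the planted term at ~3x prevalence
    set <- unique(c(sample(carriers, 48),
                    sample(setdiff(universe, carriers), 152)))
    te <- term_enrichment(set, ann, universe)
    if (te$term_id[1] == planted) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
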