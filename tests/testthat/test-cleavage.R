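test_that("extract_flanks maps P3-P3' around both scissile bonds", {
  fl <- extract_flanks(6, 9, "ACDEFGHIKLMNPQRS")  # peptide GHIK
  expect_equal(fl$N, c(P3 = "D", P2 = "E", P1 = "F", `P1'` = "G",
                       `P2'` = "H", `P3'` = "I"))
  expect_equal(fl$C, c(P3 = "H", P2 = "I", P1 = "K", `P1'` = "L",
                       `P2'` = "M", `P3'` = "N"))

  # peptide starting at position 2: P1 = residue 1, P2/P3 absent
  fl2 <- extract_flanks(2, 5, "ACDEFGHIK")
  expect_equal(unname(fl2$N[c("P3", "P2", "P1")]),
               c(NA, NA, "A"))
  expect_equal(unname(fl2$N[c("P1'", "P2'", "P3'")]), c("C", "D", "E"))

  # exact C-terminal peptide: no C-cut hydrolysis event
  fl3 <- extract_flanks(6, 9, "ACDEFGHIK")
  expect_true(all(is.na(fl3$C)))
  # exact N-terminal peptide: no N-cut
  fl4 <- extract_flanks(1, 4, "ACDEFGHIK")
  expect_true(all(is.na(fl4$N)))
})

test_that("compute_background pools residue frequencies", {
  expect_equal(unname(compute_background("AAAA")["A"]), 1)
  bg <- compute_background(c("AC", "CA"))
  expect_equal(unname(bg[c("A", "C")]), c(0.5, 0.5))
  set.seed(51)
  bg2 <- compute_background(replicate(5, random_protein(80)))
  expect_equal(sum(bg2), 1)
})

test_that("flank_counts conserves weights with per-position denominators", {
  seqs <- c(P1 = "ACDEFGHIKLMNPQRS")
  peps <- data.frame(
    peptide = c("GHIK", "CDEF", "MNPQRS"), protein_id = "P1",
    dataset = "D", start = c(6L, 2L, 11L), end = c(9L, 5L, 16L),
    stringsAsFactors = FALSE)
  fc <- flank_counts(toy_collection(seqs, peps), "D")
  # third peptide ends at L: C-cut excluded entirely
  expect_equal(fc$n_sites$n_sites[fc$n_sites$cut == "C" &
                                    fc$n_sites$position == "P1"], 2)
  # N-cut of peptide 2 defines P1 but not P2/P3
  ns <- fc$n_sites[fc$n_sites$cut == "N", ]
  expect_equal(ns$n_sites[ns$position == "P1"], 3)
  expect_equal(ns$n_sites[ns$position == "P3"], 2)
  # column sums equal n_sites for each position
  for (i in seq_len(nrow(fc$n_sites))) {
    sub <- fc$counts[fc$counts$cut == fc$n_sites$cut[i] &
                       fc$counts$position == fc$n_sites$position[i], ]
    expect_equal(sum(sub$count), fc$n_sites$n_sites[i])
  }
  expect_equal(sum(fc$background), 1)
})

test_that("flank_enrichment matches the closed-form example", {
  # background 0.05, 400 sites, 60 observed -> expected 20, ratio 3,
  # chi2 = (60-20)^2/20 + (340-380)^2/380 ~= 84.21, significant
  bg <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  counts <- data.frame(cut = "N", position = "P1",
                       residue = AA_ALPHABET,
                       count = c(60, rep(340 / 19, 19)),
                       stringsAsFactors = FALSE)
  tab <- structure(list(dataset = "D", counts = counts,
                        n_sites = data.frame(cut = "N", position = "P1",
                                             n_sites = 400),
                        background = bg),
                   class = "flank_count_table")
  en <- flank_enrichment(tab)
  row <- en[en$unit_type == "residue" & en$unit == "A", ]
  expect_equal(row$expected, 20)
  expect_equal(row$ratio, 3)
  expect_equal(row$chi2, (60 - 20)^2 / 20 + (340 - 380)^2 / 380,
               tolerance = 1e-12)
  expect_equal(row$chi2, 84.21, tolerance = 1e-3)
  expect_true(row$significant)
  # a residue at its expected share is not significant
  row2 <- en[en$unit_type == "residue" & en$unit == "C", ]
  expect_lt(row2$ratio, 2)
  expect_false(row2$significant)
})

test_that("observed == expected gives ratio 1 everywhere, nothing flagged", {
  bg <- stats::setNames(rep(0.05, 20), AA_ALPHABET)
  counts <- data.frame(cut = "C", position = "P2", residue = AA_ALPHABET,
                       count = rep(20, 20), stringsAsFactors = FALSE)
  tab <- structure(list(dataset = "D", counts = counts,
                        n_sites = data.frame(cut = "C", position = "P2",
                                             n_sites = 400),
                        background = bg),
                   class = "flank_count_table")
  en <- flank_enrichment(tab)
  res <- en[en$unit_type == "residue", ]
  expect_equal(res$ratio, rep(1, 20))
  expect_false(any(en$significant))
})

test_that("enrichment ratios are invariant to duplicating the study", {
  set.seed(52)
  seqs <- stats::setNames(replicate(10, random_protein(100)),
                          sprintf("P%02d", 1:10))
  peps <- do.call(rbind, lapply(1:60, function(i) {
    pid <- sample(names(seqs), 1)
    s <- sample(2:85, 1)
    data.frame(peptide = substr(seqs[[pid]], s, s + 8), protein_id = pid,
               dataset = "D", start = s, end = s + 8L,
               stringsAsFactors = FALSE)
  }))
  en1 <- flank_enrichment(flank_counts(toy_collection(seqs, peps), "D"),
                          min_sites = 1)
  seqs2 <- c(seqs, stats::setNames(seqs, sprintf("Q%02d", 1:10)))
  peps2 <- rbind(peps, transform(peps, protein_id = sub("P", "Q",
                                                        protein_id)))
  en2 <- flank_enrichment(flank_counts(toy_collection(seqs2, peps2), "D"),
                          min_sites = 1)
  m <- merge(en1, en2, by = c("cut", "position", "unit_type", "unit"))
  expect_equal(m$ratio.x, m$ratio.y, tolerance = 1e-9)
  expect_equal(m$observed.y, 2 * m$observed.x, tolerance = 1e-9)
})
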