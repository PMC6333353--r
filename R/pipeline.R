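# Run orchestration: all stages, one output directory of TSVs, a JSON
# summary and a log. All thresholds live in the config.

#' Default pipeline configuration
#'
#' @return named list of thresholds and options: `control` dataset,
#'   membrane-class boundaries (`tm_low`, `tm_high`), expression threshold
#'   (`rpkm_threshold`) and strata edges, cleavage filter (`fold_min`,
#'   `alpha`, `min_sites`), terminal windows (`c_window`, `n_window_range`),
#'   pKa table, t-test mode, enrichment floor.
#' @export
default_config <- function() {
  list(control = "TAP+",
       pka = "bjellqvist",
       t_mode = "pooled",
       tm_low = 0.10, tm_high = 0.40,
       rpkm_threshold = 8,
       rpkm_bins = c(0, 0.5, 1, 2, 4, 8, 16, 32, Inf),
       fold_min = 2, alpha = 0.001, min_sites = 20,
       c_window = 20L, n_window_range = c(12L, 34L),
       min_universe = 5,
       enrichment_method = "chi2",
       background_scope = "dataset")
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), config)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full characterization pipeline
#'
#' Executes collection assembly, feature profiling, dataset overlap,
#' positional decile mapping, terminal residue composition, cleavage-flank
#' enrichment and abundance/annotation analysis, writing one directory of
#' TSV tables plus `summary.json` and `run.log`. Outputs are deterministic
#' given inputs and config.
#'
#' @param proteome path to FASTA, or data.frame `id`, `seq`.
#' @param peptides path to TSV, or data.frame (see [read_peptides()]).
#' @param expression optional path or data.frame `protein_id`, `rpkm`.
#' @param annotations optional path or data.frame of TM/SIGNAL spans.
#' @param gaf optional path to a GAF 2.x file, or data.frame `protein_id`,
#'   `term_id`, `aspect`.
#' @param out_dir output directory (created if missing); NULL to skip
#'   writing.
#' @param config named list overriding [default_config()], or a path to a
#'   YAML/JSON file of overrides.
#' @return object of class `tapfree_report`: list of all stage results.
#' @export
run_pipeline <- function(proteome, peptides, expression = NULL,
                         annotations = NULL, gaf = NULL, out_dir = NULL,
                         config = list()) {
  cfg <- read_config(config)

  proteins <- stage("read_proteome",
                    if (is.character(proteome)) read_proteome(proteome)
                    else proteome)
  pep <- stage("read_peptides",
               if (is.character(peptides)) read_peptides(peptides)
               else peptides)
  expr <- stage("read_expression",
                if (is.character(expression)) read_expression(expression)
                else expression)
  ann <- stage("read_annotations",
               if (is.character(annotations)) read_annotations(annotations)
               else annotations)
  go <- stage("read_gaf",
              if (is.character(gaf)) read_gaf(gaf) else gaf)

  collection <- stage("build_collection",
                      build_collection(proteins, pep, expr, ann))
  labels <- sort(unique(collection$occurrences$dataset))
  if (!cfg$control %in% labels)
    stop("stage 'config' failed: control dataset '", cfg$control,
         "' absent from the peptide table (present: ",
         paste(labels, collapse = ", "), ")", call. = FALSE)

  feats <- stage("features",
                 protein_features(collection, pka = cfg$pka,
                                  tm_low = cfg$tm_low,
                                  tm_high = cfg$tm_high))
  dists <- stage("feature_distributions",
                 feature_distributions(collection, feats,
                                       control = cfg$control,
                                       t_mode = cfg$t_mode))
  overlap <- if (length(labels) >= 2L)
    stage("dataset_overlap", dataset_overlap(collection)) else NULL

  positional <- stage("positional", do.call(rbind, lapply(labels,
    function(d) {
      pr <- positional_profile(collection, d)
      ut <- if (pr$n_total >= 50) decile_uniformity_test(pr) else
        list(statistic = NA_real_, df = NA_real_, p = NA_real_)
      pct <- 100 * pr$decile_counts / pr$n_total
      cbind(data.frame(dataset = d),
            as.data.frame(as.list(stats::setNames(
              round(pct, 4), paste0("decile_", 1:10)))),
            data.frame(exact_N_pct = 100 * pr$n_exact_N / pr$n_total,
                       exact_C_pct = 100 * pr$n_exact_C / pr$n_total,
                       n_total = pr$n_total, chi2 = ut$statistic,
                       df = ut$df, p = ut$p))
    })))

  compositions <- stage("termini_composition", {
    res <- list()
    for (d in labels) {
      seqs <- collection$proteins$seq[collection$proteins$id %in%
                                        parent_ids(collection, d)]
      res[[d]] <- list(
        C = terminal_composition(seqs, "C", cfg$c_window),
        N = terminal_composition(seqs, "N", max(cfg$n_window_range)))
    }
    res
  })
  comp_tests <- stage("termini_tests", {
    others <- setdiff(labels, cfg$control)
    rows <- list()
    for (d in others) {
      for (cl in c("GLY", "PRO", "AROMATIC")) {
        cc <- compare_composition(compositions[[d]]$C,
                                  compositions[[cfg$control]]$C, cl)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = d, end = "C", class = cl,
          positions = paste0("1-", cfg$c_window),
          mean_pct = 100 * cc$mean_a, control_mean_pct = 100 * cc$mean_b,
          t = cc$t, p = cc$p, stringsAsFactors = FALSE)
      }
      nw <- seq(cfg$n_window_range[1], cfg$n_window_range[2])
      nn <- compare_composition(compositions[[d]]$N,
                                compositions[[cfg$control]]$N, "GLY",
                                positions = nw)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, end = "N", class = "GLY",
        positions = paste(range(nw), collapse = "-"),
        mean_pct = 100 * nn$mean_a, control_mean_pct = 100 * nn$mean_b,
        t = nn$t, p = nn$p, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  cleavage <- stage("cleavage", do.call(rbind, lapply(labels,
    function(d) {
      fc <- flank_counts(collection, d,
                         background_scope = cfg$background_scope)
      en <- flank_enrichment(fc, min_sites = cfg$min_sites,
                             fold_min = cfg$fold_min, alpha = cfg$alpha)
      if (nrow(en)) cbind(dataset = d, en, stringsAsFactors = FALSE)
      else NULL
    })))

  abundance <- NULL
  if (!is.null(expr))
    abundance <- stage("abundance",
                       abundance_representation(
                         collection, reference = "proteome",
                         threshold = cfg$rpkm_threshold,
                         bin_edges = cfg$rpkm_bins))

  association <- stage("dataset_association",
                       assign_exclusive_datasets(collection))
  enrichment <- NULL
  if (!is.null(go) && nrow(go)) {
    enrichment <- stage("term_enrichment", do.call(rbind, lapply(labels,
      function(d) {
        assoc <- association$protein_id[association$dataset == d &
                                          association$associated]
        if (length(assoc) < 2L) return(NULL)
        te <- tryCatch(term_enrichment(assoc, go,
                                       universe = collection$proteins$id,
                                       min_universe = cfg$min_universe,
                                       method = cfg$enrichment_method),
                       error = function(e) NULL)
        if (is.null(te)) NULL else
          cbind(dataset = d, as.data.frame(te), stringsAsFactors = FALSE)
      })))
  }

  report <- structure(
    list(collection = collection, features = feats, distributions = dists,
         overlap = overlap, positional = positional,
         compositions = compositions, composition_tests = comp_tests,
         cleavage = cleavage, abundance = abundance,
         association = association, enrichment = enrichment,
         config = cfg),
    class = "tapfree_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to a directory of TSVs
#'
#' Emits features.tsv, summaries.tsv, overlap.tsv, positional.tsv,
#' composition.tsv, classes.tsv, cleavage.tsv, abundance.tsv,
#' association.tsv, enrichment.tsv, summary.json and run.log. Outputs are
#' byte-identical across reruns on the same inputs.
#'
#' @param report a `tapfree_report`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(report$features, p("features.tsv"))
  write_tsv(report$distributions$summary, p("summaries.tsv"))
  write_tsv(report$distributions$tests, p("feature_tests.tsv"))
  if (!is.null(report$overlap)) {
    write_tsv(report$overlap$venn, p("overlap.tsv"))
    write_tsv(report$overlap$pairwise, p("overlap_pairwise.tsv"))
  }
  write_tsv(report$positional, p("positional.tsv"))
  comp <- do.call(rbind, lapply(names(report$compositions), function(d) {
    do.call(rbind, lapply(c("C", "N"), function(e) {
      m <- report$compositions[[d]][[e]]
      df <- as.data.frame(as.table(m$freq), stringsAsFactors = FALSE)
      names(df) <- c("position", "residue", "frequency")
      cbind(dataset = d, end = e, df, stringsAsFactors = FALSE)
    }))
  }))
  write_tsv(comp, p("composition.tsv"))
  write_tsv(report$composition_tests, p("classes.tsv"))
  if (!is.null(report$cleavage)) write_tsv(report$cleavage, p("cleavage.tsv"))
  if (!is.null(report$abundance)) {
    write_tsv(report$abundance$strata, p("abundance.tsv"))
    write_tsv(report$abundance$folds, p("abundance_folds.tsv"))
  }
  write_tsv(report$association, p("association.tsv"))
  if (!is.null(report$enrichment))
    write_tsv(report$enrichment, p("enrichment.tsv"))

  sizes <- report$collection$dataset_sizes
  summary <- list(
    package_version = as.character(utils::packageVersion("tapfree")),
    stages = c("io_model", "features", "positional",
               "termini_composition", "cleavage", "abundance_go",
               "stats_report"),
    n_proteins = nrow(report$collection$proteins),
    n_occurrences = nrow(report$collection$occurrences),
    dataset_sizes = as.list(sizes),
    n_parental = length(parent_ids(report$collection)),
    config = report$config[!vapply(report$config, is.function,
                                   logical(1))])
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  log <- c(paste("tapfree version:",
                 as.character(utils::packageVersion("tapfree"))),
           paste("R version:", R.version.string),
           "thresholds:",
           paste0("  ", names(report$config), " = ",
                  vapply(report$config, function(v)
                    paste(format(v), collapse = ","), character(1))))
  writeLines(log, p("run.log"))
  invisible(out_dir)
}

#' @export
print.tapfree_report <- function(x, ...) {
  cat("tapfree report\n")
  print(x$collection)
  cat("\nPositional profiles:\n")
  print(x$positional[, c("dataset", "exact_N_pct", "exact_C_pct", "chi2",
                         "p")], digits = 4, row.names = FALSE)
  if (!is.null(x$abundance)) {
    cat("\n"); print(x$abundance)
  }
  sig <- x$cleavage[x$cleavage$significant & x$cleavage$unit_type ==
                      "residue", , drop = FALSE]
  cat("\nSignificant cleavage-flank enrichments (residue level):",
      nrow(sig), "\n")
  invisible(x)
}
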