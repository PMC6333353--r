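#!/usr/bin/env Rscript
# Thin command-line wrapper over the tapfree package.
#
#   Rscript scripts/tapfree.R simulate --preset paperlike --seed 1 --out DIR
#   Rscript scripts/tapfree.R report --in DIR --out DIR2 [--config FILE]
#
# `simulate` writes proteome.fasta, peptides.tsv, expression.tsv,
# annotations.tsv (if any), annotations.gaf and truth.json.
# `report` runs the full characterization pipeline on such a directory.

suppressMessages(library(tapfree))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: tapfree.R <simulate|report> [options]")
cmd <- args[1L]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

if (cmd == "simulate") {
  preset <- get_arg("--preset", "paperlike")
  seed <- as.integer(get_arg("--seed", "1"))
  out <- get_arg("--out", "simulated")
  params <- switch(preset,
                   paperlike = paperlike_params(seed = seed),
                   stop("unknown preset: ", preset))
  simulate_ligandome(params, out_dir = out)
  cat("simulated study written to", out, "\n")
} else if (cmd == "report") {
  indir <- get_arg("--in")
  if (is.null(indir)) stop("report needs --in DIR")
  out <- get_arg("--out", file.path(indir, "report"))
  cfg <- get_arg("--config", NULL)
  ann <- file.path(indir, "annotations.tsv")
  run_pipeline(proteome = file.path(indir, "proteome.fasta"),
               peptides = file.path(indir, "peptides.tsv"),
               expression = file.path(indir, "expression.tsv"),
               annotations = if (file.exists(ann)) ann else NULL,
               gaf = file.path(indir, "annotations.gaf"),
               out_dir = out,
               config = if (is.null(cfg)) list() else cfg)
  cat("report written to", out, "\n")
} else {
  stop("unknown command: ", cmd)
}
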