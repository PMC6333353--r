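# tapfree

Characterization of the parental proteins of TAP-independent MHC class I
ligands.

## The problem

Most peptides presented by MHC class I molecules are cut out of cytosolic
proteins by the proteasome and pumped into the endoplasmic reticulum by the
TAP transporter. Cells with defective TAP still present a reduced ligandome
through alternative, TAP-independent processing routes, and the proteins
that feed those routes are not a random sample of the proteome: they tend
to be small, membrane-embedded or secretory, highly expressed, and their
ligands cluster at the ends of the parent chain — many coincide exactly
with the protein C-terminus, so a single endoproteolytic cut suffices to
release them.

`tapfree` implements the computational side of that characterization for
anyone analyzing eluted-ligand datasets labelled by processing route
(TAP+, TAP-C, TAP-NC, HLA-II or any other labels):

* **Placement and bookkeeping** — peptides are located on their parent
  proteins (all exact matches, fractional weight 1/k for k placements),
  byte-identical proteins are deduplicated under one identifier, and
  parental-protein overlaps between datasets are tabulated.
* **Protein features** — length, isoelectric point (Henderson–Hasselbalch
  bisection over the ionizable side chains D, E, C, Y, H, K, R plus free
  termini; Bjellqvist/ExPASy pKa set by default), Kyte–Doolittle GRAVY
  index, transmembrane residue fraction with the four membrane classes
  (0, <10%, 10–40%, >40%), per-dataset summaries and Student/Welch t-tests
  against a control dataset.
* **Positional mapping** — each ligand's midpoint is assigned to a decile
  of its parent's length (`ceil(10·m/L)`); exact-N and exact-C terminal
  fractions are reported and decile histograms are tested against the
  uniform expectation n/10 (chi-square, df = 9).
* **Terminal composition** — position-specific residue frequencies of the
  last (or first) w residues of the parental proteins, with class-level
  (Gly, Pro, aromatic) comparisons between datasets.
* **Cleavage-site specificity** — the P3–P3′ flanks (Schechter–Berger
  nomenclature) of both scissile bonds of every ligand are tallied and
  normalized by the natural residue occurrence of the parental proteins;
  a residue or residue class is flagged when it is ≥2-fold enriched with
  p < 0.001 (one-degree chi-square, observed-vs-rest).
* **Abundance and annotation** — parents are stratified by mRNA abundance
  (RPKM), fold-representation above a threshold (default RPKM > 8) is
  compared against a reference set at the protein and peptide level, and
  dataset-associated proteins (strictly contained, or observed/expected
  share ratio > 2) are tested for flat annotation-term enrichment
  (chi-square or hypergeometric, with Benjamini–Hochberg q-values
  alongside the raw p-values).
* **Synthetic studies** — a generator simulates a proteome, expression
  table, annotation file and labelled peptidomes with planted, recoverable
  biases (exact-terminal fractions, terminal-decile mass,
  abundance-sampling exponent, flank motifs via rejection sampling,
  annotation-term plants), so the entire pipeline is testable without any
  external dataset.

## Worked example

Simulate a four-dataset study at a published-study scale and run the full
pipeline:

```r
library(tapfree)

sim <- simulate_ligandome(paperlike_params(seed = 7))
report <- run_pipeline(sim$proteins, sim$peptides, sim$expression,
                       sim$tm_annotations, sim$annotations,
                       out_dir = "results")
print(report)
```

```
tapfree report
ligand_collection: 1500 proteins, 5975 peptide occurrences
datasets (weighted peptide counts):
  HLA-II   2799.0
  TAP-C    428.0
  TAP-NC   623.0
  TAP+     2125.0

Positional profiles:
 dataset exact_N_pct exact_C_pct    chi2         p
  HLA-II      0.2144      0.0000  24.140 4.085e-03
   TAP-C      0.4673     22.4299 354.710 6.160e-71
  TAP-NC      0.4815     24.2376 452.393 8.828e-92
    TAP+      0.3294      0.4235   9.499 3.926e-01

Abundance representation (reference: proteome, RPKM > 8)
 dataset n_measured fold_protein fold_peptide   chi2         p
  HLA-II       1150        1.221        1.706  17.74 2.533e-05
   TAP-C        289        2.509        2.891 207.72 4.324e-47
  TAP-NC        490        1.505        1.692  39.48 3.318e-10
    TAP+       1050        1.282        1.737  26.32 2.891e-07
```

Reading this: the TAP-independent datasets place ~22–24% of their ligands
exactly at the parent C-terminus (the planted value is 21%) and their
decile histograms reject uniformity decisively (the "smile" of terminal
enrichment), while the TAP+ control is compatible with uniform placement
(p = 0.39) and has essentially no exact-terminal ligands. The abundance
panel shows the planted, stronger coupling of TAP-C sampling to mRNA
abundance: parents with RPKM > 8 are 2.5-fold over-represented relative
to the whole proteome, versus 1.3-fold for TAP+.

`run_pipeline()` writes every result as a TSV (features, summaries,
overlap, positional, composition, classes, cleavage, abundance,
association, enrichment) plus `summary.json` and `run.log` into
`out_dir`; reruns on the same inputs are byte-identical.

Single-protein utilities work standalone:

```r
gravy("MKWVTFISLLLLFSSAYS")        # 1.288889
isoelectric_point("MKWVTFISLLLLFSSAYS")  # 8.59
```

A thin command-line wrapper is provided:

```sh
Rscript scripts/tapfree.R simulate --preset paperlike --seed 1 --out study/
Rscript scripts/tapfree.R report --in study/ --out study/report/
```

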