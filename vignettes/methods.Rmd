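---
title: "Methods: characterizing parental proteins of TAP-independent MHC class I ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing parental proteins of TAP-independent MHC class I ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapfree)
```

# Scope and data model

`tapfree` characterizes the *parental proteins* of MHC ligands — the
proteins from which eluted peptides were proteolytically derived — across
several labelled datasets (by convention `TAP+`, `TAP-C`, `TAP-NC`,
`HLA-II`, but labels are free). Its inputs are the field's plain-text
formats: a FASTA proteome, a peptide TSV (`peptide`, `protein_id`,
`dataset`, optional `allele`, `start`, `end`), an expression TSV
(`protein_id`, `rpkm`), an optional TM/signal span TSV and a GAF 2.x
annotation file. All coordinates are 1-based inclusive.

Three conventions run through everything:

* **Placement.** A peptide is an exact substring of its parent. Stated
  coordinates are verified; otherwise all exact matches are found and the
  peptide's unit of evidence is split fractionally (weight $1/k$ over $k$
  placements), so weighted peptide counts always sum to the number of
  input peptides. Peptides whose stated parent does not contain them are
  dropped with a warning, never silently — mirroring the small fraction of
  unplaceable identifications any curated compilation contains.
* **Deduplication.** Proteins with byte-identical sequences are merged
  under the lexicographically smallest identifier (a 100%-identity,
  100%-length criterion). No similarity threshold below 100% is applied:
  cross-database reconciliation by alignment is out of scope, and
  identifier joins with an exact-sequence fallback replace it.
* **Determinism.** Nothing in the analysis path draws random numbers;
  rerunning any stage on the same inputs yields byte-identical tables.

# Protein features

The GRAVY index is the arithmetic mean of per-residue Kyte–Doolittle
hydropathy values; `X` residues are excluded from the mean. The
isoelectric point solves $Q(\mathrm{pH}) = 0$ for the
Henderson–Hasselbalch net charge over the ionizable side chains
(D, E, C, Y, H, K, R) and the free termini. $Q$ is strictly decreasing in
pH, so bisection on $[0, 14]$ converges unconditionally; we iterate to
0.002 pH and the test suite checks agreement with an independent
0.001-step grid scan to 0.01 pH. The pKa set is a parameter: the
Bjellqvist/ExPASy table is the named default (the values behind the
ProtParam-style pI most datasets report) and the EMBOSS set ships
alongside; swapping tables shifts pI by up to ~0.5 pH for basic proteins,
which is why the choice is explicit rather than buried.

Membrane character is summarized as the fraction of residues inside
transmembrane spans, binned into four classes: exactly 0 (non-membrane),
below 10% (peripheral), 10–40% inclusive (intermediate), above 40%
(integral). Only the two outer boundaries are scientifically meaningful
("<10%", ">40%"); assigning both boundary points to the closed middle bin
is a declared convention, as is every histogram bin edge (all
config-driven, none hard-coded). TM and signal spans are *ingested* from
annotation TSVs; running predictors such as TMHMM or SignalP is a
non-goal.

Per-dataset feature comparisons use the classic pooled two-sample t-test
by default — the test named in the statistical tradition these analyses
follow — with Welch's correction behind a flag (`t_mode = "welch"`);
membrane-class composition is compared to the control dataset's
proportions by chi-square.

# Positional mapping

A ligand spanning $[s, e]$ on a parent of length $L$ is assigned the
decile $\lceil 10\,m/L \rceil$ of its midpoint $m = (s+e)/2$, clamped to
$[1, 10]$. The midpoint rule is a declared convention for peptides that
straddle a decile boundary: it is deterministic, matches the "position"
language of the analysis, and a fractional-spreading alternative would
change nothing qualitatively while making counts non-integer at source.
Exact-terminal ligands (start = 1, or end = L) are reported as separate
fractions *and* still contribute to deciles 1/10: the two statistics are
logically independent.

Uniformity is tested by chi-square against $n/10$ per bin (df = 9), with
a configurable floor (default $n \ge 50$) and a low-expected-count
warning flag. One calibration caveat is inherent to the discreteness of
placement: a peptide of length $\ell$ cannot have its midpoint within
$(\ell-1)/2$ residues of either end, so on parents whose decile width is
comparable to $\ell$ the outer bins are slightly depleted even under
uniform placement. The test's size calibration in the suite therefore
uses parents long relative to the peptides (L = 2000, 8–14-mers), where
this depletion is negligible; on very short proteins the test is mildly
anti-conservative against uniformity.

# Terminal residue composition

Composition matrices count each *unique parental protein once* (a
peptide-weighted mode exists behind a flag, but the terminal-composition
question is about the proteins, not about peptide sampling depth). For
the C-terminal end, position 1 is the last residue; windows default to
20 positions. Proteins shorter than the window contribute only to the
positions they cover, so every position carries its own denominator and
each position's frequencies form a probability vector. The N-terminal
analysis (positions 12–34 by default) counts position 1 as the first
residue, initiator Met included.

Class comparisons (Gly, Pro, aromatic = F/W/Y) report the mean class
frequency over a position range in each dataset and a two-tailed t-test
treating positions as paired observations; a per-position chi-square on
raw counts is emitted alongside. Pairing by position is a declared
convention for comparing "average percentage over a window" claims; the
per-protein binary alternative is available through the per-position
counts.

# Cleavage-site flanking analysis

Every placed ligand defines up to two hydrolysis events: the N-cut
(between parent positions $s-1$ and $s$) and the C-cut (between $e$ and
$e+1$). Following Schechter–Berger nomenclature, P3–P1 lie upstream of
the cut and P1′–P3′ downstream; for the N-cut P1′–P3′ are the first
peptide residues, for the C-cut P3–P1 the last. A ligand at the exact
C-terminus has no C-cut (that is the point of exact-terminal ligands:
one cut suffices), so the site is excluded wholly; likewise an exact-N
ligand has no N-cut. Sites near a protein end keep the positions they do
define — per-position denominators — rather than being dropped, which
matters because terminal-biased datasets would otherwise lose most of
their informative sites.

Counts are normalized by the natural residue occurrence of the dataset's
own parental proteins (whole-proteome background by flag — the two
interpretations of "the selected proteins" are both supported). For each
(cut, position, residue) cell: expected = background × sites, ratio =
observed/expected, and a one-degree chi-square of observed-vs-rest
against expected-vs-rest. The reported *significant* flag is the joint
filter ratio ≥ 2 and p < 0.001; both thresholds are config. Residues are
additionally grouped into ten biochemical classes (aromatic, aliphatic,
hydroxyl, amide, acidic, basic, Gly, Pro, Cys, Met). The chi-square is
used to match the analysis tradition; it is slightly anti-conservative
for rare residues at small site counts, which is why the joint filter
(not the p-value alone) defines a hit and why positions with fewer than
20 sites are skipped by default.

# Abundance and annotation enrichment

RPKM strata default to edges {0, 0.5, 1, 2, 4, 8, 16, 32, ∞}; only the
">8" threshold carries meaning, the remaining edges are display bins.
Proteins without an expression value form an explicit *unmeasured*
stratum excluded from fold computations. Fold-representation above the
threshold is computed at protein level (fraction of parental proteins)
and peptide level (weighted peptide fraction), against either the whole
proteome or a control dataset.

A protein is *associated* with a dataset if strictly contained in it, or
if its observed peptide share exceeds twice the share expected from the
dataset's size: $(c_d/\sum c) / (\mathrm{size}_d/\sum \mathrm{size}) > 2$.
Containment logically implies association (the ratio rule can never veto
it — this is tested as an invariant). Associated sets are tested for
flat term enrichment against a universe: detected vs expected counts,
2×2 chi-square (hypergeometric by flag), terms with fewer than 5
universe members skipped. Raw p-values are primary — the analysis
tradition applies no multiple-testing correction — but
Benjamini–Hochberg q-values are always emitted in a parallel column.
DAVID-style clustering of enriched terms and GO-DAG propagation are
non-goals (true-path propagation would require the ontology graph, which
is deliberately not an input).

# The synthetic-data generator

The generator exists so that every stage has a ground truth. It draws
i.i.d. residue sequences (Swiss-Prot-like composition by default) with
log-normal lengths truncated to [50, 5000], log-normal RPKM, optional
transmembrane tracks, and a pool of background annotation terms. Each
dataset then samples peptides:

* parent ∝ rpkm^γ (γ = 0 is abundance-blind), times a configurable boost
  for planted annotation terms;
* placement: with probability π_exactC the peptide ends exactly at the
  parent C-terminus; with π_exactN it starts at residue 1; with π_term
  its midpoint falls in the terminal deciles (1–2 vs 10, split ρ_N :
  1−ρ_N); otherwise uniform. Non-exact placements are clamped away from
  both exact termini, so the exact fractions are controlled solely by
  their parameters;
* an optional flank motif (cut, position, residue class, fold) is imposed
  by *rejection sampling*: out-of-class candidate sites are accepted with
  probability $b = (1-fq)/(f(1-q))$ where $q$ is the background class
  frequency, which realizes the requested fold $f$ among accepted sites
  (feasible iff $fq < 1$; infeasible folds raise an error). Sequences are
  never edited, so residue backgrounds remain honest. The placement type
  is drawn *before* the rejection loop — re-drawing it would let the
  motif filter inflate the exact-terminal fractions.

One integer seed drives a named pseudorandom stream per sub-generator
(lengths, sequences, rpkm, membrane, terms, one per peptidome), so adding
a generator never perturbs the others and outputs are byte-identical
under a fixed seed.

The `paperlike` preset encodes the scenario scale this package is aimed
at: dataset sizes 2125 (TAP+), 428 (TAP-C), 623 (TAP-NC), 2799 (HLA-II);
π_exactC = 0.21 for both TAP-independent sets; TAP-C terminal mass
π_term = 0.29 with ρ_N = 0.69, calibrated so that about 30% of TAP-C
peptides fall in the two N-terminal deciles and about 35% in the
C-terminal decile; abundance exponents 0.3 for TAP+/TAP-NC/HLA-II and
0.8 for TAP-C; a 2.5-fold C-cut P1′ Gly motif on TAP-C; one
immune-response-like term planted at 3× sampling boost on HLA-II; 9-mer
centred lengths for TAP+, broader 8–14 for TAP-independent sets, 13–17
for HLA-II. These are scenario defaults chosen once, not reproductions
of any particular experiment.

What the generator deliberately does **not** emulate: MHC binding motifs
(anchor residues), mass-spectrometry detectability bias, spliced
peptides, per-dataset protein-length differences, correlated
protein-term structure in the ontology, or TM-segment association with
any dataset. Passing round-trip tests therefore demonstrates that the
pipeline recovers what was planted under honest noise — not that real
ligandomes satisfy the generator's independence assumptions.

# Numerical and testing choices

* Bisection tolerance 0.002 pH for pI; weighted counts are never rounded
  except at report time; decile boundaries use `ceiling` with clamping.
* Degenerate t-test inputs (zero variance) are answered explicitly
  (p = 1 for equal means, p = 0 with a `degenerate` flag otherwise)
  instead of erroring mid-pipeline.
* Zero-background cells with nonzero observations report an infinite
  ratio and are flagged, never silently dropped.
* The test suite sizes its simulations to run on one CPU in a few
  minutes: type-I calibration uses 1000 replicates of n = 1000 placements
  on an L = 2000 parent; parameter-recovery checks use 100 seeds at
  n = 1000 (exact-C) and n = 500 (flank motif); the null
  false-discovery check uses 200 replicates of n = 400; the round trip
  runs the full `paperlike` scale (1500 proteins, 5975 peptides) twice
  to verify byte-identical reruns.

# Known limitations

* The pipeline joins expression and annotations by identifier only; if
  your peptide compilation and expression atlas use different identifier
  namespaces, reconcile them upstream.
* The decile-uniformity test is mildly anti-conservative on very short
  parents (see above).
* The 2×2 chi-square for term enrichment and the one-degree flank test
  are approximations; exact alternatives (hypergeometric) are available
  by flag and recommended when expected counts are small.
* Composition comparisons treat positions as independent paired
  observations; real terminal sequences have local dependencies
  (signal-anchor segments, C-terminal motifs) that this ignores.
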