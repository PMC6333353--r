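# Scales, alphabets and class definitions shared across the pipeline.

#' Standard amino-acid alphabet
#'
#' The 20 proteinogenic residues in one-letter code. 'X' (unknown) is
#' tolerated by the readers and flagged, but is never part of this alphabet.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values used for the GRAVY index (grand average of
#' hydropathy). Positive values are hydrophobic.
#' @export
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' pKa tables for isoelectric-point calculation
#'
#' Named sets of dissociation constants for the ionizable side chains
#' (D, E, C, Y, H, K, R) and the free termini. `bjellqvist` is the
#' ExPASy/ProtParam default; `emboss` reproduces the EMBOSS `iep` values.
#' Each entry is a named numeric vector with elements `nterm`, `cterm`,
#' `D`, `E`, `C`, `Y`, `H`, `K`, `R`.
#' @export
PKA_TABLES <- list(
  bjellqvist = c(nterm = 7.50, cterm = 3.55,
                 D = 4.05, E = 4.45, C = 9.00, Y = 10.00,
                 H = 5.98, K = 10.00, R = 12.00),
  emboss     = c(nterm = 8.60, cterm = 3.60,
                 D = 3.90, E = 4.10, C = 8.50, Y = 10.10,
                 H = 6.50, K = 10.80, R = 12.50)
)

#' Biochemical residue classes
#'
#' Groupings used for terminal-composition and cleavage-flank reporting.
#' @export
RESIDUE_CLASSES <- list(
  AROMATIC  = c("F", "W", "Y"),
  ALIPHATIC = c("A", "V", "L", "I"),
  HYDROXYL  = c("S", "T"),
  AMIDE     = c("N", "Q"),
  ACIDIC    = c("D", "E"),
  BASIC     = c("K", "R", "H"),
  GLY       = "G",
  PRO       = "P",
  CYS       = "C",
  MET       = "M"
)

# Swiss-Prot-like background residue frequencies (renormalized to sum 1);
# default composition for the synthetic proteome generator.
UNIPROT_FREQS <- local({
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38,
         Q = 3.93, E = 6.72, G = 7.07, H = 2.27, I = 5.91,
         L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.74,
         S = 6.64, T = 5.36, W = 1.10, Y = 2.92, V = 6.86)
  f <- f[sort(names(f))]
  f / sum(f)
})

# Canonical dataset labels; the pipeline accepts arbitrary labels but the
# defaults mirror the four antigen-processing routes under study.
DATASET_LABELS <- c("TAP+", "TAP-C", "TAP-NC", "HLA-II")

FLANK_POSITIONS <- c("P3", "P2", "P1", "P1'", "P2'", "P3'")
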