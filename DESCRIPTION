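Package: tapfree
Title: Characterization of Parental Proteins of TAP-Independent MHC Class I Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterizing the parental proteins of MHC class I
    ligands presented independently of the transporter associated with antigen
    processing (TAP). Places eluted peptides on their parent proteins, profiles
    physicochemical features (length, isoelectric point, Kyte-Doolittle GRAVY,
    transmembrane residue fraction), maps ligand positions onto parent-length
    deciles with exact-terminal statistics, analyzes position-specific residue
    composition of protein termini, computes background-normalized residue
    enrichment at the P3-P3' flanks of both scissile bonds (Schechter-Berger
    nomenclature), stratifies parental proteins by mRNA abundance (RPKM), and
    performs flat annotation-term enrichment. A synthetic proteome/peptidome
    generator with planted, recoverable biases makes every stage testable
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
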