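Package: ssTEA
Title: Subfamily-Specific Two-Entropy Analysis of GPCR Transmembrane
    Alignments
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies receptor-specific ligand-binding residue positions
    in class A G-protein coupled receptors from a gap-free multiple
    sequence alignment of the seven transmembrane helices. Implements the
    subfamily-specific two-entropy analysis (ss-TEA) score, which compares
    the Shannon entropy of each Ballesteros-Weinstein alignment column
    inside a subfamily of the receptor tree against the entropy over all
    sequences outside it, together with the supporting machinery: per-helix
    gap-free profile alignment with score calibration and helix-order
    repair, p-distance/neighbor-joining subfamily trees, a semi-logarithmic
    ROC (pROC AUC) performance measure with curated reference sets of
    ligand-binding positions, and a synthetic-alignment generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
biocViews: Alignment, SequenceMatching, Classification, Proteomics
RoxygenNote: 7.3.3
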