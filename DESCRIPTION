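Package: tilecrispr
Title: Cas9 Tiling-Screen Design, Dropout Scoring and Reporter Quantification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for protein-domain-resolution CRISPR/Cas9 tiling screens:
    exhaustive enumeration of NGG-PAM guides over a coding sequence with
    cut-site-to-residue mapping, pooled-screen dropout scoring (frequency-ratio
    CRISPR scores with control-anchored z normalization), sliding-window
    projection of guide scores onto protein coordinates with depleted-segment
    calling and domain annotation, dual-fluorescence reporter statistics for
    stop-codon readthrough and drug-induced degradation (MFI ratios, fold
    changes versus vehicle, exact rank-sum and Kruskal-Wallis tests), and a
    synthetic-data generator producing count tables and flow-event tables with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
biocViews: CRISPR, FunctionalGenomics, PooledScreens, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
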