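Package: stoplossr
Title: Functional Impact Prediction for Stop-Loss Variants with C-Terminal Extensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting variants that disrupt translation
    termination. Enumerates every possible single-nucleotide substitution,
    insertion and deletion at a stop codon, scans the 3' UTR for the nearest
    in-frame downstream stop codon to derive the resulting C-terminal
    extension peptide, assembles a 37-dimensional feature vector combining
    variant-level annotation scores with transcript- and peptide-level
    properties (length, amino-acid composition, Kyte-Doolittle and
    Miyazawa-Jernigan hydrophobicity, aggregation propensity), trains a
    cross-validated random-forest pathogenicity classifier, calibrates
    benign/pathogenic score thresholds with a two-component Gaussian mixture
    likelihood-ratio rule, and assigns ACMG/AMP-style evidence codes
    (PVS1/PS1/PM4/PM5/PP3). A seeded synthetic-cohort generator makes the
    whole pipeline testable without external annotation databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    randomForest,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
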