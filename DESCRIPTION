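Package: snpimpact
Title: Allele-Specific Analysis of Motif Disruption Effects on TF Binding and Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploiting discriminatory single-nucleotide variants
    (discSNPs) between phenotypically matched cell lines to quantify, at
    base-pair resolution, how transcription-factor motif disruption affects
    ChIP-seq binding signal and chromatin accessibility. Includes a simplified
    pileup-based zygosity caller with block smoothing, PWM log-odds motif
    scanning with per-SNP disruption scoring (Score_max/DiffScore) and
    random-walk threshold optimization, percent-residual-binding impact
    statistics with bootstrap confidence intervals and permutation (maxT)
    multiple-testing correction, a contextual-motif logistic-regression
    predictor of TF occupancy with shuffled-PWM controls and DeLong ROC
    comparison, a CRISPR amplicon deletion-allele enrichment scanner, and a
    synthetic-data generator that produces every input with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    limma,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
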