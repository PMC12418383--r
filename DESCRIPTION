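Package: utr5xpress
Title: Modeling the Impact of 5'UTR Sequences on Protein Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for predicting translation efficiency and protein output
    from 5' untranslated region (5'UTR) sequences. Implements biologically
    grounded feature extraction (k-mer composition, GC metrics, upstream AUG
    counts, codon usage, and RNA secondary-structure descriptors via
    ViennaRNA's RNAfold), an extremely randomized trees regressor with the
    associated hyperparameter grid search, a fully convolutional
    soft-classification network trained with a Kullback-Leibler loss and the
    Lion optimizer, a 29-bin probabilistic expression codec, greedy
    incremental sequence clustering for dataset compression with
    representative test-set construction and percentage- or count-based
    training-subset selection, cross-validation and bias diagnostics, and
    reference-well normalization of replicate-plate bioluminescence
    measurements. A synthetic-data module generates 5'UTR libraries with
    planted cluster structure and feature-linked labels so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: ViennaRNA (RNAfold on the PATH) for RNA
    secondary-structure features
Config/testthat/edition: 3
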