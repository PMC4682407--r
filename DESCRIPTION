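Package: scmseq
Title: Scoring Card Method for Interpretable Protein Sequence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains interpretable scoring-card classifiers for two-class
    protein sequence problems from dipeptide composition. A scorecard assigns
    each of the 400 ordered dipeptides a propensity score in [0, 1000]; a
    query sequence is scored by the composition-weighted sum of its dipeptide
    scores and classified against a trained threshold. Initial scores are the
    min-max normalised difference of mean class dipeptide compositions and
    are refined by an intelligent genetic algorithm whose crossover uses
    two-level orthogonal arrays, with a fitness balancing ranking performance
    (AUC) against conservation of the initial amino-acid propensities.
    Includes stratified cross-validation, Mann-Whitney comparison of class
    dipeptide compositions, correlation mining of learned amino-acid
    propensities against AAindex physicochemical scales, per-residue
    propensity tracks with sliding-window (hydropathy-style) profiles, PDB
    B-factor annotation, and a seeded Markov-chain generator of labelled
    synthetic sequence sets with planted dipeptide biases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    optparse,
    pROC,
    seqinr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
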