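Package: cdkphos
Title: Quantitative Analysis of CDK Substrate Phosphorylation Dynamics
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative analysis of cyclin-dependent kinase
    (CDK) substrate phosphorylation from SILAC phosphoproteomics time
    courses. Provides substrate calling from kinase-inactivation decay
    experiments (one-phase exponential decay fits with anomaly screening),
    per-site CDK-activity thresholds from inhibitor titrations (constrained
    four-parameter logistic fits with robust outlier removal), in vivo
    kinase-rate estimation from washout assays, temporal classification of
    substrates across the cell cycle (early/mid/late), a G1/S
    cyclin-specificity score, kinase consensus-motif classification and
    annotation enrichment. A synthetic-data generator emulating
    MaxQuant-style phosphosite tables with known kinetic ground truth makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
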