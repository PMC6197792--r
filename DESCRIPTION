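Package: ncfger
Title: Neighbor-Based Collaborative Filtering with Global-Effect Removal
    for Anti-Cancer Drug-Response Imputation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Imputes unknown anti-cancer drug responses in a cell-line by
    drug matrix (log IC50 or activity area) by neighborhood collaborative
    filtering after Bayesian-shrunk removal of global effects (overall
    mean, per-cell-line and per-drug offsets).  Neighbors are ranked by a
    fused similarity combining molecular-feature correlation (expression
    Pearson correlation for cell lines, fingerprint Jaccard for drugs)
    with response-profile correlation, shrunk by overlap support;
    interpolation weights are solved from shrunk normal equations under a
    non-negativity constraint.  Includes a synthetic data generator with
    the additive-plus-low-rank structure the model assumes, repeated
    entry-wise 10-fold cross-validation with per-drug PCC/RMSE and
    sensitive/resistant-quartile metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
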