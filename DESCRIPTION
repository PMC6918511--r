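Package: metaheterosis
Title: Metabolome-Based Prediction of Yield Heterosis in Hybrid Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts better-parent heterosis for yield per plant (BPH-YPP) of
    rice hybrids from untargeted LC-MS metabolite profiles of their parents.
    Implements the full workflow: replicate averaging, sum normalization and
    autoscaling of metabolite tables; parental-mean predictive variables;
    NIPALS partial least squares (PLS1) regression with latent-factor selection
    by adjusted R-square and variable importance in projection (VIP); PLS-DA
    screening of analytes between high- and low-heterosis subgroups with
    permutation testing and cross-validation; population-structure dissection
    by PCA with interval selection of core hybrids for mixed-population
    training sets; mean-VIP feature sweeps, redundancy filtering and
    across-year model validation; analyte-wise differential testing with FDR
    control; and a synthetic two-population generator with known ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
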