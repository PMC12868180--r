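Package: pssmapr
Title: Stability Analysis for Probabilistic Stimulation Sweet-Spot Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic stimulation mapping in deep brain
    stimulation (DBS) research. Computes probabilistic sweet spots (PSS)
    from outcome-labeled volumes of tissue activated (VTAs) with three
    voxel-wise statistical methods (Wilcoxon signed-rank with
    Benjamini-Hochberg FDR correction, Wilcoxon with permutation-based
    family-wise correction, and a directional Bayesian one-sample test),
    followed by patient/stimulation occurrence filters and small-cluster
    removal. Quantifies the geometric variability of sweet spots under an
    additive patient-resampling and stimulation-subsampling scheme,
    detects stability points on the resulting metric curves, and fits a
    Bayesian logistic regression on total stimulation count to derive the
    minimum patient-by-stimulation boundary for geometrically stable
    maps. Includes a synthetic-cohort generator with trajectory-clustered
    VTAs and a ground-truth sweet spot so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
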