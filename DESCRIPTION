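Package: achmap
Title: Locating Atrial Parasympathetic Innervation Sites from Electrogram Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: In silico toolbox for locating atrial parasympathetic (acetylcholine
    release) innervation sites from grids of unipolar electrograms. Provides 2D
    human atrial monodomain tissue simulation (Courtemanche myocytes with the
    acetylcholine-activated potassium current IKACh, MacCannell active
    fibroblasts, diffuse fibrosis, atrial-fibrillation remodeling), a unipolar
    electrogram forward model with electrode footprint averaging, filtering and
    SNR-controlled noise injection, and a two-stage amplitude-threshold
    detection algorithm (fibrosis from depolarization amplitude, acetylcholine
    sites from repolarization amplitude) with ROC-based threshold optimization
    and accuracy/sensitivity/false-positive-rate evaluation. Fast analytic
    phantom generators make the electrogram and detection stages testable
    without solving the tissue equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pROC,
    readr
Config/testthat/edition: 3
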