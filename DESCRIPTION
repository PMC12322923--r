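Package: vdmap
Title: Vessel Distance Mapping and Arterial Supply Territory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vessel distance mapping (VDM) of labeled artery and
    cortex volumes: exact anisotropic Euclidean distance transforms per
    artery, winner-takes-all parcellation of a cortical region of interest
    into arterial supply territories, supply volume fractions, vessel
    pattern and vessel dominance classification with threshold sweeps,
    majority-vote fusion of territory parcellations into pattern-specific
    atlases, and statistical assessment of vascular configuration against
    cortical thickness (OLS with HC3 robust errors, nested model
    comparison, covariate adjustment). Includes a synthetic phantom
    generator with analytic ground-truth territories and cohort covariate
    tables so the full pipeline can be exercised and validated without
    subject imaging data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    sandwich,
    car,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
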