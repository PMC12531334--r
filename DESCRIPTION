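Package: vitrials
Title: Semi-Synthetic Virtual Interventional Trials for Individualized
    Prescriptive Inference in Ischaemic Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates biologically structured synthetic cohorts (grey-matter
    grids, functional networks, treatment-responsive subnetworks, lesions,
    surrogate tractography and disconnectomes), simulates two-arm virtual
    interventional trials under randomized, observably confounded, or
    unobservably confounded treatment allocation with tunable treatment and
    recovery effects, infers individualized prescriptions with S-/T-learner
    meta-learners over lesion representations of varying expressivity
    (PCA, NMF, autoencoders, vascular-atlas baselines), and evaluates
    prescriptive fidelity with balanced accuracy and the precision in
    estimation of heterogeneous effects (PEHE) under patient-grouped
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    RNifti,
    ranger,
    xgboost,
    kernlab,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
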