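Package: nirsimpair
Title: Detecting THC Impairment from Prefrontal fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying acute THC impairment from
    prefrontal functional near-infrared spectroscopy (fNIRS) recorded during an
    n-back working-memory task. Covers the 20-channel prefrontal probe and its
    five regions of interest, modified Beer-Lambert conversion of dual-wavelength
    optical densities to oxy-/deoxyhemoglobin, block-design epoching, a 95-value
    temporal feature map, sliding-window dynamic connectivity, a recurrent
    connectivity classifier stacked with gradient-boosted trees, grouped
    stratified cross-validation with binomial significance testing against the
    null-information rate, timepoint-wise paired group statistics with
    Benjamini-Hochberg correction, and a synthetic cross-over study generator
    (THC vs placebo visits, heart rate and self-rated "high" trajectories,
    latent impairment) that makes every stage testable without access to
    participant data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    signal,
    pracma,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
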