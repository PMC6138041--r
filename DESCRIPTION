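Package: boldretest
Title: Test-Retest Reliability Analysis for Short fMRI Control Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for assessing the test-retest
    reliability of short event-related fMRI control tasks. Generates the
    two five-minute task variants' trial schedules, simulates two-session
    BOLD cohorts with known reliability structure, fits voxel-wise general
    linear models with extended motion confounds and discrete-cosine
    high-pass drift terms, and computes voxel-wise and region-of-interest
    ICC(3,1) reliability statistics with Fisher-z standardization,
    permutation cluster-extent thresholding, activation-threshold sweeps
    and activation/reliability overlap summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
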