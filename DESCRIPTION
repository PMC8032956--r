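Package: ratfc
Title: Rodent Resting-State fMRI Denoising, Artifact Cleaning and
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end processing and analysis toolkit for rodent
    resting-state BOLD fMRI at the single-session level: Marchenko-Pastur
    PCA removal of thermal noise with residual-normality and tSNR quality
    control, slice-timing correction, spatial smoothing and high-pass
    filtering, single-session spatial ICA with supervised (FIX-style)
    artifact classification and regression-based cleaning, ROI functional
    connectivity with global-signal partial correlation, Fisher-z
    within-group variability scoring, and network-based-statistic
    permutation testing of group differences. A synthetic 4D BOLD phantom
    generator with known ground truth makes every stage testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
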