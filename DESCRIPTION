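Package: musdecode
Title: Decoding Musicianship from Encoded fMRI Responses to Naturalistic Music
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A group-membership decoding framework for naturalistic-stimulus
    fMRI. Region-averaged BOLD time series are encoded from stimulus feature
    time series by participant-wise linear regression; each group's encoded
    responses are modelled as time-point-wise diagonal Gaussians; per-region
    log-likelihood ratios between group models serve as features for a linear
    discriminant classifier evaluated by repeated stratified held-out-pair
    cross-validation. Includes a stimulus-feature preparation chain
    (hemodynamic response convolution, spline detrending, temporal smoothing,
    downsampling, varimax-rotated components), a synthetic-cohort generator
    with planted discriminative regions, performance and inferential
    statistics, and delimited-matrix input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
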