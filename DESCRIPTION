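Package: maternalfc
Title: Longitudinal Resting-State fMRI Analysis of the Postpartum Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study local and global functional brain adaptations
    after childbirth. Implements voxel-level resting-state fMRI metrics
    (fractional amplitude of low-frequency fluctuations, local correlation,
    global correlation) with the confound-regression, detrending and
    bandpass steps they require; non-parametric cluster-mass permutation
    inference for group contrasts with covariates; subject-level spatial
    colocalization of deviation maps with hormone and neurotransmitter
    receptor distributions using Spearman correlations and group-permutation
    nulls; and longitudinal statistics (linear mixed models with linear and
    quadratic time, per-timepoint ANCOVAs, paired tests, Hedges' g,
    within-subject standardization, interaction models, FDR correction and a
    regression-toward-the-mean diagnostic). A synthetic-data generator
    reproduces the statistical structure of a two-group longitudinal
    postpartum design so that every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
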