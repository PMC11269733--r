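Package: eventfmri
Title: Analysis Pipeline for Rapid Event-Related Video fMRI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing, simulating and analysing rapid
    event-related fMRI experiments with short naturalistic video stimuli.
    Builds balanced multi-session trial schedules with null trials and
    adjacency constraints, simulates BOLD volume series with known ground
    truth (double-gamma responses, AR(1) noise, slow drift, temporal-epoch
    lags, memorability-modulated amplitudes), estimates trial-wise finite
    impulse response (FIR) betas with discrete-cosine high-pass filtering
    and AR(1) prewhitening, and carries the betas through split-half
    reliability with Spearman-Brown correction and a permutation criterion,
    probabilistic-map region-of-interest definition, searchlight
    representational similarity analysis with noise ceilings, voxelwise
    feature encoding with PCA compression and noise normalisation,
    variance partitioning of within-video temporal epochs via adjusted
    R-squared, and memorability-response correlation, plus the shared
    group statistics (FDR, Bonferroni, binomial, ANOVA with Tukey HSD)
    these analyses report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
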