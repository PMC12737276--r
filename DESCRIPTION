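Package: ecogsleep
Title: Sleep Staging, Spectral, Coherence and Spindle Analysis for Micro-ECoG Grid Recordings
Version: 0.1.0
Authors@R: person("ecogsleep", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multichannel cortical surface (micro-ECoG)
    recordings from electrode grids: sleep staging of 4-s epochs from video motion
    and dominant-band spectral power, Welch power spectral density with radial
    basis function spatial interpolation over the 8x8 grid, magnitude-squared
    coherence across six canonical frequency bands with paired Wilcoxon plus
    false-discovery-rate change statistics, a parameterized sleep-spindle
    detector (despiking, resampling to 1024 Hz, high-pass detrending, optional
    ICA, sigma-band filtering, envelope thresholding) with amplitude, duration,
    power and density metrics, and random-intercept mixed models for metric
    comparisons. Includes a synthetic-data generator that plants a known
    hypnogram, spindle events, pairwise coherence and motion frames so every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
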