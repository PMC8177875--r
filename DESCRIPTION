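Package: megalpha
Title: Resting-State MEG Spectral Analysis of Alpha Slowing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for resting-state magnetoencephalography
    (MEG) spectral biomarkers of thalamocortical dysrhythmia, centred on
    the slow-to-fast alpha power ratio (mean power in 7-9 Hz over mean
    power in 9-11 Hz). Provides a synthetic resting-state cohort
    generator (aperiodic 1/f background, narrowband alpha oscillators,
    cardiac/ocular/powerline artifacts), a preprocessing chain
    (powerline notch, band-pass, bad-segment exclusion, signal-space
    projection of stereotyped artifacts), Welch power spectral density
    estimation with band-power, alpha-peak-frequency and
    alpha-power-ratio feature extraction at sensor and region level, and
    group statistics (two-sample permutation t tests with a shared
    permutation schedule, Benjamini-Hochberg false discovery rate
    control, Pearson correlations with covariates, and a lateralization
    index over homologous region pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
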