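Package: capcompare
Title: Comparison of Gel-Based and Dry-Electrode EEG Caps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for validating dry-electrode EEG caps
    against conventional gel-based caps. Provides standard ten-twenty and
    equidistant 64-channel montages on a spherical head model, spherical-spline
    scalp-potential interpolation to a combined 128-channel layout, Butterworth
    band-pass/notch preprocessing with automated bad-channel rating and common
    average referencing, Welch spectral analysis of resting-state alpha power,
    blink-artifact overlays and pattern-reversal visual evoked potential
    analysis with global field power (GFPt) component detection, channel
    reliability scoring, and cap-versus-cap comparison statistics (Pearson r,
    RMSD, Lilliefors and Mann-Whitney U tests). A synthetic-session generator
    produces paired gel/dry cohorts with realistic alpha rhythms, blink
    artifacts, evoked components, bad channels and cap-dependent impedances, so
    the full pipeline can be exercised without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
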