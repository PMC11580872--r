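Package: itdbias
Title: Binaural Cue Extraction and Azimuth-Estimation Bias Analysis for
    ITD Psychophysics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how interaural time differences (ITDs) map
    onto perceived sound-source azimuth. Provides a spherical-head HRIR
    generator and a CIPIC-layout reader, gammatone-filterbank extraction of
    ITD/ILD-versus-azimuth cue maps via analytic-signal phase and circular
    statistics, dichotic tone-burst stimulus synthesis with
    transition-balanced trial blocks, a calibrated simulator of per-trial
    responses for three lateralization tasks (ILD match, linear bar, azimuth
    pointer), and an analysis pipeline (per-subject summaries, z-score
    pooling, percentile bootstrap, sigmoid fitting, cubic-spline inversion
    of the acoustic map) that yields azimuth-estimation bias curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
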