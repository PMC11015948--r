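Package: icvocal
Title: Spike-Train Analysis of Inferior Colliculus Responses to Mouse
    Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for extracellular multiunit recordings from
    the mouse inferior colliculus (IC) responding to social vocalizations
    and synthetic stimuli. Converts trial spike trains to bootstrap spike
    density functions with percentile confidence intervals, classifies
    excitatory and inhibitory responses against background-firing
    percentiles, builds frequency response areas with characteristic
    frequency and bootstrap tuning-bandwidth estimates (modified-Akima
    interpolated tuning curves), scores the spectral overlap between unit
    tuning and call spectra, and applies the group statistics used for
    population comparisons (chi-square on CF histograms, Kruskal-Wallis on
    bandwidth limits, Benjamini-Hochberg step-up correction). A synthetic
    population generator produces IC-like units and inhomogeneous Poisson
    spike trains so every stage can be exercised and calibrated end to end
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
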