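Package: olfOntogeny
Title: Developmental Analysis of Insect Olfactory Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-structured analysis of developmental locust olfactory
    electrophysiology. Provides an on-disk dataset format and S4 data model
    for spike-train and analog (local field potential, electroantennogram)
    trials; electroantennogram peak extraction, within-animal normalization
    and age-comparison statistics; a projection-neuron response-complexity
    statistic built from inverse inter-spike-interval rates, Gaussian
    smoothing, lookahead/delta peak detection and epoch-transition counting;
    an odor-evoked oscillation pipeline (zero-phase 3-50 Hz bandpass, Hann
    spectrograms, trial-averaged peak-frequency extraction, burst property
    summaries) including the antennal-trimming frequency regression; and a
    seeded synthetic-data generator that emulates each recording modality
    with stored ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
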