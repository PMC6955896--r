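Package: sourcebci
Title: Source-Space EEG Analysis for Motor-Imagery Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Classifies right-hand versus right-foot motor imagery from
    multichannel EEG in cortical source space.  Provides an analytic
    three-shell spherical head model and lead field, a standardized
    (sLORETA) minimum-norm inverse operator, somatomotor region-of-interest
    aggregation, common-spatial-pattern features with a linear support
    vector machine, exhaustive ROI subset searches with occurrence
    tallies, and a seeded synthetic trial generator that plants
    class-dependent mu-band power in chosen regions over 1/f background
    activity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
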