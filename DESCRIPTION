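Package: eclosr
Title: Single-Animal Metamorphosis Timing and Population Eclosion Rhythm Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the circadian clock gates adult emergence
    (eclosion) in holometabolous insects. Provides a stochastic per-animal
    scheduling model of two competing gating hypotheses (permissive versus
    developmental), a ground-truthed synthetic generator of time-lapse image
    series and population emergence records, burst-based image-series
    reconstruction and translational stabilization, extraction of
    developmental markers (wing darkening, head-roughening indices by local
    standard deviation and patch-perimeter algorithms), onset and emergence
    detection in noisy traces, and autocorrelogram-based population
    rhythmicity statistics (rhythmicity index, period, three-way
    classification, and a valley-spacing criterion).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
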