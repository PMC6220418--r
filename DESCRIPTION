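Package: taatrack
Title: Time-Lapse Measurement of Grass Flower-Opening Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for measuring the time of day of
    anther appearance (TAA) in grass panicle time-lapse imagery. Daytime
    RGB frames are tiled into 34x34 patches and scored by a pluggable
    three-class (background/closed/open spikelet) classifier; nighttime
    infrared frames are analysed per spikelet by windowed frame
    differencing with intensity-centroid drift stabilisation to call
    opening events. Opening calls are turned into anchored cumulative
    flowering curves, smoothing-spline rates, and accession comparisons
    (one-way ANOVA and Holm-adjusted pairwise t-tests). Companion
    morphometrics cover bristle density from binary panicle masks, leaf
    midline length with day/night growth partition, and leaf emergence
    time profiles. Seeded synthetic-scene generators provide ground-truth
    inputs for every stage, and an exhaustive capture-parameter optimiser
    scores acquisition settings by detected edge count.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    nnet,
    xml2,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
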