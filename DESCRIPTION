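Package: palmripe
Title: Oil Palm Fruit Ripeness Grading from Fruit-Battery Voltage and Color Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for grading oil palm fruit ripeness from two complementary
    sensing modalities. A fruit-battery equivalent-circuit model relates the
    voltage measured across an external load resistor to the fruit's internal
    resistance, which tracks moisture content; the package analyses load
    resistance sweeps, selects the load giving the finest moisture-content
    resolution, and converts regression slopes into per-ADC-count resolution.
    A computer-vision path corrects image colors against a 16-chip reference
    chart via an affine RGB transform fitted by least squares, removes the
    background, and extracts the mean red/green ratio of the fruit. Both
    feature streams, alone and combined, are compared through a seeded,
    stratified k-fold SVM grid-search protocol. A synthetic-cohort generator
    and image renderer with full ground truth support end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
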