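Package: etaxis
Title: Quantitative Analysis of Single-Cell Electrotaxis Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying directed cell migration (electrotaxis /
    galvanotaxis) from time-lapse single-cell tracking data: per-cell
    directedness, migration speed, long-axis orientation index and area;
    directional statistics including mean resultant vectors, rose histograms
    and the two-sample Mardia-Watson-Wheeler uniform-scores test; a lumped
    resistor-network model of multi-field microfluidic electrotaxis chips;
    a synthetic-data generator (biased persistent random walks with von Mises
    headings, and elliptical label masks with axially biased orientations)
    for validating every stage of the pipeline; and an experiment runner that
    applies complete-track filtering, minimum-cohort rules and confidence
    intervals, and emits per-cell and per-group reports.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
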