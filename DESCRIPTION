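Package: spheroquant
Title: Quantitative Image Analysis of Tumor Spheroid Invasion Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Objective, reproducible quantification of spheroid invasion from
    brightfield micrographs. Thresholds for segmenting the cell-covered area
    into core, intermediate, and edge zones are set from downward peaks of the
    first derivative of a smoothed center-line intensity profile, removing the
    subjectivity of manual threshold selection. From the nested zone masks the
    package computes invasion indices A and B (edge, and edge plus
    intermediate, fractions of the cell-covered area) together with
    conventional invasion parameters (relative area and perimeter, maximum
    invasion length, detached-cell and skeleton end-point counts, volume,
    roundness, equivalent diameter). Includes a seeded synthetic spheroid
    phantom generator with known ground truth, and a batch pipeline that
    processes a time-course image series with one threshold set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
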