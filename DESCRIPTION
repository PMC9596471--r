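Package: subnanospec
Title: Processing and Identification of Sub-Nanopore Protein Nanospectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing blockade-current recordings of single
    protein or peptide molecules translocating through sub-nanometer
    diameter pores. Extracts blockade events from raw ionic-current
    traces (Axon Binary Format or TSV), resamples and normalises the
    resulting nanospectra, builds average and progressive-alignment
    consensus nanospectra, predicts theoretical nanospectra from
    peptide sequences under six amino-acid volume encodings fitted by
    linear regression, aligns empirical and theoretical nanospectra
    with a slope-constrained dynamic time warping, and estimates the
    significance of a match against random-peptide decoys. Includes a
    synthetic nanospectrum generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
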