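Package: ribotrace
Title: Simulation and Analysis of Single-Molecule Translation-Site Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-molecule translation imaging of the SunTag/MS2
    kind: a stochastic (Gillespie) simulator of ribosome loading, codon-by-codon
    elongation, frameshifting and harringtonine runoff on membrane-tethered
    mRNAs, producing per-RNA fluorescence traces and rendered movies with full
    ground truth; spot detection, particle-track linking and RNA/translation-site
    pairing; ribosome-runoff survival analysis (Kaplan-Meier with Greenwood
    confidence bounds, per-cell averaging, log-rank comparison) and inversion of
    median runoff times to region-specific elongation speeds; two-color
    frameshift classification; and steady-state quantification of translating
    RNA fractions with replicate-level statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    survival,
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
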