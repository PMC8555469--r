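Package: plvnet
Title: Phase-Locking Value Network Analysis for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for EEG functional-connectivity analysis
    of two-class motor-imagery brain-computer interface (BCI) sessions.
    Implements common average referencing, zero-phase band-pass filtering,
    a spherical-spline surface Laplacian, instantaneous phase extraction by
    complex Morlet wavelet convolution, inter-trial phase-locking values
    (PLV) per electrode pair for rest and motor-imagery windows, aggregation
    into global, inter-hemispheric, and intra-hemispheric network scales,
    and permutation-based factorial ANOVA comparing high- and low-performing
    BCI users after a median split. A synthetic cohort generator with von
    Mises phase coupling and known expected PLV provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    tibble,
    dplyr,
    data.table
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
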