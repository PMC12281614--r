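Package: srnareg
Title: Kinetic Modelling and Global Sensitivity Analysis of Bacterial
    sRNA-Mediated Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mass-action kinetic model of post-transcriptional regulation by
    bacterial small regulatory RNAs (sRNAs), covering cotranscriptional
    binding of the nascent transcript, sRNA-dependent termination and
    processing, co-degradation, sRNA recycling, and translational control.
    Provides a fast reduced steady-state solver for the log2 protein
    regulation-strength statistic, variance-based Sobol global sensitivity
    analysis on a Saltelli design with bootstrap confidence intervals,
    scenario time-course simulation of sRNA induction experiments, a
    generator of noisy synthetic observations, and single-parameter recovery
    from such data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
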