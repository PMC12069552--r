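Package: SCNComplex
Title: Cell-Type-Specific Transcription Factor Complex Signatures in the
    Arabidopsis Root Stem Cell Niche
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action modelling of heterodimer and trimer formation between
    the transcription factors WOX5, PLT3 and BRAVO in the cells of the
    Arabidopsis root stem cell niche. Relative association/dissociation rates
    are calibrated against FRET-FLIM binding fractions by a grid scan over a
    dimer ordinary differential equation, and the seven-species complex
    system is integrated to steady state per cell type to predict complex
    "signatures" for stele initials, quiescent centre, columella stem cells
    and columella cells, including a PLT3 prion-like-domain deletion
    perturbation and a panel of control simulations. Includes a synthetic
    data generator for per-nucleus fluorescence intensities, binding samples
    and TCSPC decay histograms, maximum-likelihood lifetime fitting to
    estimate binding and FRET efficiency, and the nonparametric statistics
    used for grouping (Kruskal-Wallis, Dunn's test with Benjamini-Hochberg
    adjustment and compact letter display, and Yates-corrected chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    deSolve,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
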