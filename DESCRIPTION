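Package: lunginjurynet
Title: Scale-Free Network Analysis of Heterogeneous Lung Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of spatially heterogeneous acute and
    ventilator-induced lung injury from pixel-classified histology.
    Post-processes label images into discrete injury nodes, fits
    power-law size distributions by maximum likelihood with
    Kolmogorov-Smirnov bootstrap plausibility testing, estimates
    box-counting fractal dimensions, builds seismology-style
    nearest-neighbor correlation networks over injury nodes (with and
    without simulated event times), ranks injury hubs by PageRank
    centrality, and computes magnitude-stratified secondary-injury
    ("aftershock") rate curves with bootstrap confidence intervals.
    Includes a synthetic-lobe generator so the entire pipeline is
    testable without histology.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
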