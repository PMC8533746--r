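Package: cleftQuant
Title: Synaptic Cleft Localization Classification and Confocal
    Colocalization Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the nanoscale position of extracellular-matrix
    molecules (hyaluronan, HAS2, CD44) relative to pre- and post-synaptic
    markers in single-molecule localization microscopy (dSTORM) data:
    localization rendering, maximum-intensity projection, Gaussian
    pre-blur, intensity-weighted centroids, cleft geometry, perpendicular
    intensity profiles, and a five-way centroid-distance classification
    (in cleft, near cleft, pre-/post-preferential, absent) with
    per-compartment assignment. Also implements confocal-scale
    quantification of synaptic markers: 8-bit conversion, equal-threshold
    masks, mutual-intensity colocalization, edge sampling regions,
    DAPI-normalized areas, particle statistics, and ratiometric particle
    measurement; a Shapiro-Wilk-gated two-group test; and a synthetic-data
    generator (ground-truth synapse localization clouds and confocal
    spheroid phantoms) so the whole pipeline is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
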