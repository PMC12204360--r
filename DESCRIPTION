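Package: dmskel
Title: Discrete Morse Skeletonization of Neuronal Process Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Persistence-guided discrete Morse skeletonization of 2D
    likelihood images of tracer-labeled axons. Extracts centerline graphs
    as 1-unstable manifolds of a density field via 0-dimensional persistent
    homology on the cubical grid complex, simplifies them (Otsu masking,
    maximal spanning forests, haircut pruning), decomposes skeletons into
    polyline fragments with recorded lengths, and summarizes fragments into
    areal and volumetric line densities with per-compartment length totals.
    Includes an information-theoretic surprise index (Kullback-Leibler
    divergence in bits) comparing single-neuron projection densities to
    tracer-injection densities, distance-tolerant skeleton evaluation
    (precision, recall, F1, IoU with a matching radius), and a synthetic
    phantom generator producing axon-like images with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    png,
    tiff,
    pracma,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
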