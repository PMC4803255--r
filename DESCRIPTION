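Package: embclust
Title: Expectation-Maximization Binary Clustering for Behavioural Annotation
    of Movement Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised behavioural annotation of animal movement
    trajectories by expectation-maximization binary clustering (EMbC), a
    constrained Gaussian mixture model in which cluster means are bounded
    to binary (low/high) regions of the variable space delimited by
    data-driven splitting values. Includes trajectory feature extraction
    (velocity, turning angle, windowed path statistics) with
    reliability weighting for heterogeneous sampling intervals, a classic
    unconstrained EM clustering baseline, posterior-weight label smoothing,
    a Markov-chain synthetic trajectory simulator with data-loss and
    jittering degradation protocols, confusion-matrix evaluation metrics,
    burst segmentation, and CSV/KML/GeoJSON export of annotated tracks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
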