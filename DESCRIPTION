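Package: caimetrics
Title: Quantitative Analysis of Calcium-Imaging Neuronal Ensemble Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of one-photon (miniscope)
    calcium-imaging recordings after source extraction: binarization of
    fluorescence traces into active/inactive states by four rule-based
    methods (spike, full, signal, diff), per-neuron and network activation
    metrics (burst rate, network spike rate/peak/duration), pairwise
    Pearson correlation networks with threshold sweeps and a data-derived
    strong-correlation threshold, spatial (Euclidean and radial) distance
    statistics for correlated neuron pairs, cross-session neuron tracking
    by centroid proximity with baseline-normalized stress-response
    classification, and PCA-based ensemble-state representation. Includes
    a ground-truthed synthetic recording generator (Poisson activation
    events, GCaMP6f-like transients, controllable pairwise coupling,
    multi-session series) so every analysis stage is testable without raw
    recordings, plus a thin group-comparison reporting stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    igraph,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
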