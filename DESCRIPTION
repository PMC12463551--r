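Package: neurocomm
Title: Rhythm-Gated Communication-Subspace Analysis for Dual-Region Spike Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying low-dimensional communication between two
    simultaneously recorded neural populations (hippocampal CA1 and prefrontal
    cortex). Implements mean-matched reduced-rank regression with
    cross-validated dimensionality estimation, canonical correlation analysis
    with a shared/local (aligned/orthogonal) decomposition, oscillation-state
    windowing of band-limited LFP power, multitaper coherence and weighted
    phase lag index, behavioral decoding from canonical variates, and manifold
    geometry of behavior-binned pseudopopulations. Includes a synthetic
    session generator that plants known low-rank, theta-gated communication
    so that every stage of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    lme4,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
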