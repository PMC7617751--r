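Package: hipplamina
Title: Laminar Hippocampal LFP Analysis and Channel-Depth Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel local field potential (LFP)
    recordings spanning the hippocampal CA1-to-dentate-gyrus axis. Detects
    sharp-wave ripples and dentate spikes with physiological acceptance
    checks, extracts theta oscillations by masked empirical mode
    decomposition with per-cycle validation and interpolated phase, computes
    current source density (CSD) profiles and CSD-based anatomical layer
    landmarks, builds a two-dimensional ISOMAP embedding of channel waveform
    features with a cross-animal layer trajectory, out-of-sample projection
    and linearisation, profiles theta-nested gamma oscillations, and
    quantifies spike-phase coherence with occupancy normalisation and
    spike-shift surrogate tests. A synthetic laminar-session generator with
    full ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    mclust,
    igraph,
    class,
    splines,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
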