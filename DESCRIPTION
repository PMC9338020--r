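Package: orgMEA
Title: Spiking and Oscillatory Network Analysis for Organoid Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end analysis of spontaneous electrical activity recorded from
    human brain organoids on high-density microelectrode arrays. Takes spike-sorted
    single units and local field potential (LFP) voltage traces and computes
    interspike-interval regularity statistics, population-burst dynamics and
    burst-to-burst similarity, directed functional connectivity from the spike time
    tiling coefficient (STTC) with latency gating, surrogate null models and
    edge-distribution model selection, theta-band oscillation correlation and lag
    maps, imaginary coherence with coherent-pocket detection, and spike-theta phase
    locking with Rayleigh statistics. Includes a synthetic-data generator that
    produces spike trains and LFPs with embedded ground-truth connectivity and
    phase coupling for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    minpack.lm,
    igraph,
    cluster,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
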