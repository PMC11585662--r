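Package: meaconnect
Title: Functional Connectivity and Directionality Analysis for
    Two-Compartment Microelectrode-Array Recordings
Version: 0.1.0
Authors@R:
    person("MEA", "Analytics", email = "mea@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spike trains recorded from organoid
    assembloids cultured on an 8x8 microelectrode array split into two
    compartments (midbrain organoid, MO, and striatum organoid, StrO) by a
    microfluidic divider. Computes pairwise synchrony with the spike time
    tiling coefficient (STTC), conduction delays from 0.5-ms probability
    cross-correlograms with a mean + 5 SD significance gate, propagation
    speeds, per-electrode directionality vectors, and the assembloid-level
    connection-establishment verdict. Includes adaptive-threshold spike
    detection from raw voltage traces, basal-activity metrics (spike count,
    inter-spike interval, burst frequency), a batch-normalisation / IQR
    outlier / hypothesis-testing statistics layer, and a synthetic
    two-compartment recording generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
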