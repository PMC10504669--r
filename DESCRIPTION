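Package: spotcall
Title: Spot-Based Barcode Decoding and Quality Control for Multiplexed FISH
Version: 0.1.0
Authors@R: person("spotcall", "developers", role = c("aut", "cre"),
    email = "spotcall@example.org")
Description: Decodes combinatorially barcoded single-molecule FISH spot data
    (seqFISH-style) by linking detected spots across hybridization rounds.
    Implements an exhaustive candidate-barcode decoder with score-based
    selection, greedy maximum-independent-set conflict resolution, staged
    search radii, precision/recall mode presets, and single-round
    error correction for Hamming-distance-2 codebooks. Ships an automated
    quality-control metric suite (off-target count thresholds, per-cell
    false-positive rates, per-round/channel spot statistics, transcripts
    per cell, Ripley's K spatial-randomness test), elbow-point threshold
    selection for single-molecule FISH spot-count curves, and a synthetic
    spot-data generator with known ground truth for benchmarking.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
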