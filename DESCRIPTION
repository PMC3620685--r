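Package: tmbench
Title: Benchmarking Membrane Helix Topography and Topology Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation engine for benchmarking transmembrane-helix
    topography and topology predictions against reference annotations
    derived from high-resolution protein structures. Implements the full
    metric hierarchy (per-protein, per-segment, helix-boundary and
    per-residue scores, Matthews correlation coefficient and segment
    overlap (Sov) scoring), reconciliation between OPM-style and
    PDBTM-style membrane annotation conventions, Hobohm algorithm-2
    redundancy reduction and attribute-based dataset selection, plus a
    synthetic fixture generator that produces membrane-protein topologies
    and predictions with controlled, logged errors so that every metric
    has an independently computable expected value.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
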