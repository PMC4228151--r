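Package: meicall
Title: Detection of Non-Reference Mobile Element Insertions from Short-Read Alignments
Version: 0.1.0
Authors@R: person("meicall", "developers", role = c("aut", "cre"), email = "meicall@example.org")
Description: Detects active non-reference mobile element insertions (Alu, L1,
    SVA, HERV-K) from coordinate-sorted BAM files using a combination of
    discordant read-pair clustering and soft-clipped read breakpoint
    refinement. Candidate reads are aligned against a mobilome of family
    consensus sequences and tested for polyA/polyT tails; same-side anchors
    are clustered, 5'/3' clusters are joined into insertion events with
    target site duplication or deletion calls, and predictions are filtered
    against reference mobile element annotation, satellite regions and
    support thresholds. Includes a truth-driven read simulator that plants
    insertions with TSDs, polyA tails, truncation and zygosity into a
    synthetic reference and emits flag-consistent BAMs, so sensitivity and
    positive predictive value can be measured without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    Biostrings,
    Rsamtools,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
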