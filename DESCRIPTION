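Package: peakscape
Title: Downstream Analysis of Multi-Factor ChIP-seq Peak Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses of called ChIP-seq peaks for several
    transcription factors and histone marks on one genome: megabase-segment
    peak/gene density landscapes, inter-peak gap statistics against a
    random-occurrence null, peak-width and TSS-proximity classes, anchor-offset
    aggregation profiles with analytic random baselines, pairwise peak
    co-occupancy and co-bound region derivation, histone-signature (enhancer
    state) annotation, and stratified two-condition expression-shift summaries.
    Includes a seed-deterministic synthetic-landscape generator with planted
    clustering, co-binding, domain alternation and expression structure so that
    every analysis stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
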