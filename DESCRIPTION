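Package: auxrescan
Title: Cis-Element Scanning and Enrichment Analysis of Auxin-Responsive Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scans gene upstream regions for degenerate consensus motifs and
    spaced-dyad (everted-repeat) cis-elements such as the combined auxin
    response element TGTC[N11-13]GACA, the G-box CACGTG and PIF-type boxes,
    reduces occurrences to per-promoter presence calls, and tests motif
    enrichment between promoter classes with exact contingency statistics.
    Includes strand-aware fixed-length upstream extraction from a genome plus
    GFF3 annotation, background promoter sampling, and a synthetic-promoter
    generator with planted motifs and full ground truth so the whole pipeline
    is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
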