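Package: offtargetr
Title: CRISPR/Cas9 Off-Target Site Prediction with Segmented Mismatch
    Scoring and Chromatin Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts and ranks potential CRISPR/Cas9 off-target binding
    and cleavage sites. Enumerates candidate protospacers in a reference
    genome within a mismatch budget on both strands, filters by PAM class
    (GGG/NGG/NNG), scores candidates with a three-segment position-weighted
    match/mismatch model that distinguishes single from consecutive
    mismatches, and optionally adds a chromatin-accessibility bonus derived
    from multi-cell-type DNase I hypersensitivity peak tracks. Includes
    grid-search training of the segment weights against gold-standard site
    sets, a benchmarking harness (top-N containment overlap, random-region
    enrichment simulation), sgRNA design for short regions, and a seeded
    synthetic-fixture generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
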