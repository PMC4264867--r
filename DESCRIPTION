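Package: mirseed
Title: Functional Cost of MicroRNA Seed-Region Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how nucleotide changes in the 7-nt seed region
    (mature positions 2-8) of a microRNA alter its predicted and observed
    target-gene spectrum. Provides seed extraction and pairwise Hamming
    distances over a mature-miRNA panel, a canonical-site (8mer, 7mer-m8,
    7mer-A1, 6mer) seed-match predictor for 3'UTR pools plus readers for
    precomputed prediction tables (miRanda-mirSVR score filtering,
    TargetScan/PicTar-style lists), cosine-similarity overlap of target sets
    grouped by seed mismatch class, a SAM-style permutation-FDR differential
    expression pipeline (presence filtering, annotation filtering,
    signal-to-noise probe-set collapse, up/down gene lists, chi-square
    comparison of overlap vs cost), cross-species target overlap through an
    ortholog map, and synthetic-data generators with recorded ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
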