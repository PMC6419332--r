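Package: refconcord
Title: Cross-Assembly SNV Liftover and Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lift single-nucleotide variant (SNV) calls between two genome
    assembly versions using UCSC chain files, quantify conversion success,
    classify converted calls against directly-called variants as concordant,
    position-discordant or genotype-discordant, and characterize discordant
    SNVs by confidence stratum, read depth and reference-allele base
    composition. Includes a seeded synthetic-data generator that builds
    assembly pairs related by a known edit script together with consistent
    chain files, diploid call sets and an injected-discordance ledger, so
    every pipeline statistic has an exact or closed-form expected value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, rtracklayer, S4Vectors, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
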