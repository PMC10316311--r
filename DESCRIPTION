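Package: citruskit
Title: Retrotransposon Insertion Genotyping and Strip-Based Cultivar
    Identification for Citrus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for building target cultivar-specific DNA identification
    kits from retrotransposon insertion polymorphisms. Simulates
    transposon-display sequencing libraries with known ground truth;
    preprocesses reads (adapter trimming, mean-quality filtering, fixed-length
    trimming, duplicate collapsing); clusters insertion-site flanking
    sequences with a seeded Hamming-distance clusterer; calls binary
    presence/absence genotypes with a per-cultivar read-fraction threshold;
    screens cultivar-specific and polymorphic markers; finds minimal
    AND-combination marker sets by exhaustive search (with a greedy fallback);
    and assembles multiplex-PCR diagnostic kits for chromatographic
    printed-array strips, predicting band patterns and diagnosing samples.
    Ships the published genotype and marker tables for 26 Japanese citrus
    cultivars as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    S4Vectors,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
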