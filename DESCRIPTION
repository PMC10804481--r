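Package: centroscan
Title: Centromere-Proximal Meiotic Crossover Mapping and Zone Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping meiotic crossovers in recombinant plant
    populations and analysing centromere-proximal recombination
    suppression. Implements population-level SNP marker filtering,
    sliding-window crossover calling from allele-depth matrices with
    read-level boundary refinement and sample quality control, windowed
    genetic maps, delineation of non-recombining (NRZ) and 1-cM
    low-recombining (LRZ) zones, fluorescent-reporter (FTL) genetic
    distance estimation, KASP genotype-transition crossover calling with
    hotspot and coldspot detection, permutation tests for interval
    overlap and nucleotide diversity, and a synthetic-data generator that
    emulates backcross and F2 resequencing populations, seed-fluorescence
    tables, and KASP plates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
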