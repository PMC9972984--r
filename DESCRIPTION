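Package: somascape
Title: Somatic Mutation Landscape Analysis for Paired Tumour-Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome somatic small-variant calls
    from paired tumour-normal cancer cohorts. Provides variant prioritization
    (quality, population allele frequency, functional consequence, germline
    subtraction, novelty classification) with per-stage accounting; tumour
    mutational burden and hypermutation classification; microsatellite
    instability group statistics; 96-channel trinucleotide mutation catalogs
    with signature refitting (non-negative least squares) and de novo
    extraction (non-negative matrix factorization); simplified significantly
    mutated gene and hotspot-clustering driver tests; and rule-based matching
    of somatic alterations to drug response and resistance annotations. A
    seeded synthetic cohort generator with ground-truth labels makes every
    stage testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pracma,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
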