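Package: cobelr
Title: Screening Personal Genomes for Erosion of Conserved Transcription
    Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls conserved binding site eroding loci (CoBELs) in a
    personal genome: scans a reference genome with a position weight
    matrix library using MATCH-style min-max normalised scores, keeps
    sites conserved across a multiple species alignment (species count,
    neutral branch length and shuffled-motif conservation p-value
    filters), intersects them with an individual's ancestrally polarised
    single nucleotide variants, and reports loci where the derived
    allele lowers predicted binding affinity. Enriched gene functions
    and phenotypes next to the loci are found with a GREAT-style
    binomial test over basal-plus-extension regulatory domains and a
    companion hypergeometric gene test, and assessed against matched
    control permutations, cohort occurrence rates and a constrained
    medical-history shuffling test. Includes a synthetic data generator
    that plants conserved, erodible sites near genes of a chosen
    ontology term so the whole screen is testable at toy scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
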