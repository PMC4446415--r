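Package: varthesaurus
Title: Thesaurus-Based Annotation of Variants in Repetitive Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interrogating genetic variation in low-mappability
    regions of a genome. Builds a "thesaurus" table enumerating pairs of
    similar genomic regions from a reference sequence using a terminal-seed
    ungapped all-mapper, then uses the table to annotate called variants with
    links to alternative sites, organize linked calls into clusters, and
    evaluate call sets with thesaurus-aware performance measures (thesaurus
    true positive rate, pooled B-allele frequency, apparent error rates).
    Includes a simulator for repeat-family genomes with planted single
    nucleotide variants, tiled and shotgun error-model reads, a minimal
    pileup variant caller, and a command-line interface covering the whole
    simulate-build-call-annotate-evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
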