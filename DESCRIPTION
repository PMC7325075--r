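Package: gcpsr
Title: Multilocus Genealogical Concordance and Mating-Type Segregation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genealogical concordance phylogenetic species
    recognition (GCPSR) in fungi. Reads per-locus multiple sequence
    alignments and sample metadata, computes per-locus and per-species
    nucleotide diversity and site classifications, builds neighbor-joining
    gene trees with nonparametric bootstrap support, scores per-species
    monophyly against a species phylogeny to produce a conflict matrix with
    per-locus conflict percentages, flags putative hybrid individuals by
    supported foreign-clade nesting and species-merger patterns, tests 1:1
    mating-type idiomorph segregation among single-ascospore isolates, and
    includes a multilocus sequence simulator (HKY85 on species trees with
    planted introgression events) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
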