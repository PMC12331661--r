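Package: qtnbreed
Title: Marker-Assisted Selection Models and Breeding-Scheme Simulation
    over Trait-Associated QTN Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-association analysis chain for multi-environment field
    trials of inbred germplasm panels: descriptive statistics, balanced
    analysis of variance with method-of-moments variance components and
    broad-sense heritability; per-environment marker-assisted selection
    (MAS) models fitted by multiple regression on -1/+1 coded quantitative
    trait nucleotide (QTN) genotypes, with superior-allele classification
    and superior-allele counts; a stochastic forward simulator of
    half-diallel single-cross breeding programs (meiosis with Haldane
    linkage, selfing to F7, pedigree and bulk selection); and selection of
    optimal cross-by-scheme combinations from genotype-value distributions.
    Includes a synthetic-data generator emulating a multi-environment
    replicated trial of an inbred panel so the whole chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
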