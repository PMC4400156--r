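Package: ploidycall
Title: Contig Ploidy Estimation and Allele Dosage Calling from Short-Read
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the ploidy of each contig or scaffold of a genome
    assembly from whole-genome shotgun alignments, using a generative
    likelihood over allele-dosage genotypes in which the true allele carried
    by each read is a latent Bernoulli draw and sequencing errors are priced
    by a logistic error model with quality-score, neighboring-quality and
    GG-context features. Calls biallelic variants with per-position dosage
    posteriors and a Phred-like significance score, fits the sequencing-error
    model from alignments of monomorphic samples, and includes a polyploid
    paired-end read simulator with truth tables so the whole pipeline can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
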