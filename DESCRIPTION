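Package: srnapipe
Title: Small RNA-Seq Tag Annotation, Differential miRNA Expression and
    Novel miRNA Discovery
Version: 0.1.0
Authors@R:
    person("srnapipe", "developers", email = "srnapipe@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-library small RNA sequencing
    studies without replicates: read cleaning and adapter trimming, tag
    collapsing, priority-rule annotation against ncRNA/miRNA/repeat/exon/
    intron references, TPM normalisation with an exact conditional
    binomial test for differential miRNA expression, novel miRNA precursor
    calling by hairpin minimum-free-energy folding, miRNA:mRNA duplex
    hybridisation energy target prediction with extreme-value p-values,
    and hypergeometric term enrichment with Bonferroni correction. A
    seeded synthetic-data generator produces reference bundles and FASTQ
    libraries with a ground-truth manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stringi,
    stats,
    utils,
    methods,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
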