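Package: plexQTLseq
Title: Plexity-Aware QTL-seq for Autopolyploid Bulked-Segregant Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bulked-segregant QTL mapping (QTL-seq) for autotetraploid F1
    populations using simplex or duplex donor variants. Provides closed-form
    tetrasomic segregation distributions, plexity-selecting variant filters
    on parental SNP-indices, Monte-Carlo F1 null distributions for
    depth-conditional Delta(SNP-index) confidence bands and P values,
    sliding-window aggregation with directional P99 variant counts, and
    candidate-region calling. Includes a full autotetraploid bulked-segregant
    simulator (bivalent meiosis with Haldane crossovers, dosage-dependent
    phenotypes, tail bulks, binomial read sampling, multi-sample VCF output)
    and allele-dosage (plexity) genotyping from qPCR, fragment-analysis and
    amplicon-sequencing assays with consensus calls and segregation
    chi-square tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
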