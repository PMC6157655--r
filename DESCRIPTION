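Package: islandscan
Title: Genomic Islands of Divergence from SNP Data: Phi(ST) Outlier Scans,
    Bayesian Admixture and Introgression
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting genomic islands of divergence between
    closely related taxa from diploid biallelic SNP genotype matrices.
    Implements per-locus AMOVA-based Phi(ST) (Weir-Cockerham variance
    components), classification of outlier loci lying three standard
    deviations above the mean, stratification of loci into standard-deviation
    bins, a from-scratch Gibbs-sampling Bayesian admixture model for ancestry
    estimation and hybrid introgression quantification, a randomization test
    for annotation enrichment among outliers, genotype input/output in VCF,
    Structure and genepop formats with the associated read-quality, depth and
    call-rate filters, and a hierarchical Balding-Nichols simulator that
    generates genotype matrices with planted islands of divergence and
    admixed hybrids for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    vcfR,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
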