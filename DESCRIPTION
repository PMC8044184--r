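Package: jointsnv
Title: Joint Multi-Sample Bayesian Somatic SNV Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Upgrades permissive per-sample somatic single-nucleotide-variant
    (SNV) call sets into a joint multi-sample call set with higher sensitivity
    at low variant allele frequency. Implements a Bayesian graphical model over
    a matched normal and m tumor samples: per-sample pileup likelihoods with
    Phred-scored sequencing errors, marginalization of the latent variant
    allele frequency under a truncated-uniform prior, a linear-time joint
    marginal over all 2^m sample-indicator vectors, maximum-likelihood tumor
    allele estimation, a Phred-scaled tumor-in-normal (TIN) contamination
    score, and empirical post-call filters (normal depth, tumor support,
    strand, SNV clusters). Includes a clone-mixture synthetic cohort generator
    with SAM/VCF fixture output, a permissive pseudo-caller, and a
    precision-recall benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
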