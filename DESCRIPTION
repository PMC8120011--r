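Package: strixpop
Title: Population Genomics of Hybridizing Owls: Filtering, Kinship,
    Hybrid Ancestry and Private-Allele Split-Time Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome population-genomic analysis of a
    two-species, four-population owl cohort (spotted owl subspecies NSO/CSO
    and barred owl populations EBO/WBO): GATK-style site and genotype
    filtering of VCF call sets including an excess-heterozygosity
    Hardy-Weinberg exact test, KING-robust kinship screening for close
    relatives, read-depth based Z/W scaffold classification and sex
    inference, diversity and differentiation statistics (pi, segregating
    sites, Tajima's D, Weir-Cockerham and Hudson F_ST), diagnostic
    fixed-difference panels for F1/backcross hybrid classification with
    mitochondrial maternal-lineage assignment, and a private-allele moment
    estimator of very recent population split times calibrated by coalescent
    simulation, with a permutation test against panmixia. A coalescent
    segment simulator generates synthetic cohorts with the same statistical
    structure so the whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    rlang,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
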