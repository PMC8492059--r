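Package: svadapt
Title: Selection Scans, Archaic Introgression Tagging, and Demographic
    Inference for Structural Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic analysis of structural-variant (SV)
    genotypes in admixed cohorts: genotype quality control (call-rate and
    one-sided Hardy-Weinberg excess-heterozygosity filters), per-population
    allele frequencies, pairwise linkage disequilibrium from unphased
    genotypes with the closed-form r-squared upper bound, an admixture-aware
    likelihood-ratio scan for component-specific allele-frequency
    differentiation, tagging of candidate archaic-introgressed SVs with a
    breakpoint-spanning diagnostic k-mer assay, a five-population
    Wright-Fisher forward simulator with selection, and sequential
    approximate Bayesian computation to infer selection parameters. Includes
    a synthetic-cohort generator (Dirichlet admixture over Balding-Nichols
    component frequencies) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    vcfR,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
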