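Package: t2drisk
Title: Multifactorial Environmental and Genetic Risk Scoring for Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A configurable odds-ratio risk engine for incident type 2
    diabetes combining environmental risk factors with a polygenic score
    built from linkage-disequilibrium-block representative SNPs. Provides
    per-factor odds-ratio lookup with medication overrides, multiplicative
    aggregation, Hardy-Weinberg normalised per-genotype odds ratios,
    evidence-based SNP catalogue filtering and block-representative
    selection with per-subject fallback, cohort exclusion cascades with
    audit trails, multi-source diabetes endpoint ascertainment,
    gene-by-environment stratified incidence tables, and paired-bootstrap
    AUC model comparison. A synthetic cohort generator emulating the
    statistical structure of a Swedish population cohort makes every
    pipeline stage testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    vcfR
Suggests:
    withr,
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
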