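Package: glycogwas
Title: Family-Based GWAS and Biomarker Analysis of the IgG N-Glycome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic association analysis of immunoglobulin G
    N-glycosylation measured by hydrophilic-interaction UPLC. Parses Oxford
    glycan nomenclature, derives the 77 IgG glycome traits (23 direct peak
    percentages plus 54 class-aggregate derived traits) from 24-peak
    chromatogram tables, and runs the full association chain: genotype and
    phenotype quality control with an exact Hardy-Weinberg test, covariate
    adjustment with rank-based inverse-normal transformation, genomic kinship
    estimation, polygenic mixed-model fitting, the family-aware mmscore
    association test with genomic-control diagnostics, inverse-variance
    meta-analysis with a PCA-based effective-number-of-traits significance
    threshold, a permutation Hotelling T-squared global glycome test, and
    case-control biomarker evaluation by ROC analysis with repeated
    split-sample cross-validation. Includes seed-deterministic simulators for
    pedigrees, genotypes, glycomes, and case-control biomarker data so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    metafor
Config/testthat/edition: 3
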