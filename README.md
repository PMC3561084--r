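# glycogwas

Family-based GWAS and biomarker analysis of the human IgG N-glycome, in R.

Glycosylation of immunoglobulin G modulates antibody effector function, and
the composition of the IgG N-glycome is heritable. Studying its genetics
requires a chain of specialised steps that general GWAS tooling does not
cover end to end: deriving a panel of 77 correlated glycosylation traits
(IGP1–IGP77) from 24 UPLC chromatogram peaks via Oxford glycan nomenclature,
testing each SNP in founder cohorts where relatives are everywhere, pooling
cohorts while controlling multiplicity across a highly correlated trait
panel, comparing whole glycomes between small groups of knockout and
wild-type animals, and validating candidate glycan traits as disease
biomarkers. glycogwas implements that chain for statistical geneticists and
glycomics analysts, together with seed-deterministic simulators so every
stage is testable without access to cohort data.

## The models at the core

* **Trait derivation.** Peak areas are normalized to percent of total
  chromatogram area; 23 direct traits plus 54 derived class-aggregate
  traits (fucosylation, galactosylation, sialylation, bisecting GlcNAc
  shares and ratios, many within the neutral fraction) are computed from a
  user-editable registry of expressions over the annotated peak table.
* **Association.** For trait z-scores *y* (covariate-adjusted, rank
  inverse-normal transformed) with genomic kinship *K* estimated from
  allele-frequency-weighted dosages, the polygenic null model is
  `Var(y) = Ω = 2K·σg² + I·σe²` (fitted by ML on the eigenbasis of 2K).
  Each SNP dosage *g*, centred by its Ω-weighted mean *g\**, is scored as
  `β = (g*ᵀΩ⁻¹r)/(g*ᵀΩ⁻¹g*)`, `se = (g*ᵀΩ⁻¹g*)^(−1/2)`, `χ² = (β/se)²`,
  the family-aware mmscore test. Calibration is tracked by the
  genomic-control factor `λ = median(χ²)/0.4549`.
* **Meta-analysis and multiplicity.** Fixed-effect inverse-variance
  pooling (`w = se⁻²`) after an imputation-quality filter (R² ≥ 0.3);
  the genome-wide threshold divides 5×10⁻⁸ by the effective number of
  independent traits from correlation-matrix PCA at 99% explained
  variance (21 components → divisor 22 → 2.27×10⁻⁹).
* **Group comparison.** Per-trait pooled-variance t-tests plus a global
  Hotelling `T² = n₁n₂/(n₁+n₂)·dᵀS⁺d` (pseudo-inverse pooled covariance)
  with an empirical p-value from permuting group labels.
* **Biomarker validation.** Logistic models with and without the glycan,
  Mann–Whitney AUC with DeLong 95% CI, and repeated stratified 2/3–1/3
  split-sample cross-validation (percentile CI over repeats).

## Worked example

```r
library(glycogwas)

## 77 glycome traits from simulated UPLC peak areas
prof <- simulate_glycome_profiles(200, seed = 2026)
igp  <- derive_all_traits(prof)
round(c(IGP48 = mean(igp[, "IGP48"]), IGP64 = mean(igp[, "IGP64"])), 2)
#> IGP48 IGP64
#> 12.61 97.91

## end-to-end association study: pedigree simulation -> VCF -> QC ->
## rank-INT -> kinship -> polygenic fit -> mmscore -> meta table
pipe <- run_synthetic_pipeline(n_families = 60, sibship_size = 4,
                               n_snps = 300, v = 0.15, h2 = 0.3, seed = 2026)
head(pipe$assoc[order(pipe$assoc$p), c("snp", "beta", "se", "p")], 3)
#>          snp       beta        se            p
#> 150 snp00150  0.7650286 0.1275441 1.995773e-09
#> 58  snp00058 -0.3385382 0.1161601 3.563616e-03
#> 239 snp00239 -0.2982824 0.1042370 4.215363e-03
pipe$top_snp == pipe$causal_snp   # the planted SNP is recovered
#> TRUE
```

The planted SNP (per-allele effect 0.64 in z-score units, i.e. 15% of
trait variance at its allele frequency) is the only genome-wide signal;
all other SNPs are null, and `pipe$lambda` stays near 1.

```r
## biomarker validation on a simulated case-control panel
cc <- simulate_case_control(101, 183, delta = 1.4, seed = 9)
panel <- evaluate_panel(cc, baseline = c("age", "sex", "admixture"),
                        biomarkers = "biomarker", cv = TRUE,
                        n_rep = 1000, seed = 10)
panel$baseline$roc
#> AUC = 0.563 (95% CI 0.492-0.634), 101 cases / 183 controls [full-data (DeLong CI)]
panel$augmented$roc
#> AUC = 0.866 (95% CI 0.823-0.908), 101 cases / 183 controls [full-data (DeLong CI)]
panel$augmented$cv
#> AUC = 0.859 (95% CI 0.794-0.917), 101 cases / 183 controls [1000-fold repeated 67/33 split CV (percentile CI)]
```

Covariates alone carry no signal (AUC ≈ 0.5); adding the biomarker lifts
the AUC to its binormal expectation Φ(1.4/√2) ≈ 0.84, and the
cross-validated mean AUC confirms the full-data estimate is not
overfitting.

See `vignettes/glycogwas-methods.Rmd` for the statistical details and
design decisions of every stage.

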