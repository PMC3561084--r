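---
title: "Statistical methods behind glycogwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind glycogwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycogwas)
```

glycogwas implements the complete computational chain for genetic analysis
of immunoglobulin G N-glycosylation: derivation of 77 glycome traits from
24 UPLC chromatogram peaks, family-aware single-SNP association with a
polygenic mixed model, meta-analysis with multiplicity control tuned to the
correlated trait panel, a small-sample multivariate group test, and
case-control biomarker validation. This vignette explains the model behind
each stage, the tunable parameters and their defaults, and the design
choices taken where the methodology is genuinely open.

## From chromatogram peaks to 77 traits

HILIC-UPLC separation of 2-AB labelled IgG glycans yields 24 peaks
(GP1–GP24) quantified as percent of total chromatogram area
(`normalize_profiles()` enforces the sum-to-100 convention). Each peak is
annotated with one or more Oxford-notation structures
(`default_peak_table()`); where several structures co-elute, the *major*
contributor to fluorescence intensity decides class membership in derived
traits, and minor structures are stored but never aggregated.

The trait panel comprises 23 direct peak percentages and 54 derived
percentages and ratios over structural classes (core fucose, bisecting
GlcNAc, galactose and sialic-acid counts), many of them within the neutral
(asialylated) fraction. Two points deserve emphasis:

* **23 direct traits from 24 peaks.** The default registry merges the two
  early co-eluting peaks GP2 and GP3 into one direct trait (IGP2), which is
  the only mapping consistent with the published trait anchors (IGP8 is
  GP9, IGP19 is GP20, IGP48 is GP9 as a share of the neutral fraction)
  while preserving the conservation property that direct traits of one
  sample sum to 100. A strict 1:1 map of 24 peaks to 24 direct traits is
  available via `default_trait_registry(direct_map = "one_to_one")`.
* **Registry completeness.** The formulas for the derived traits that are
  pinned down by published descriptions (the neutral-fraction percentages,
  the fucosylation/bisection shares such as IGP63–IGP69, the sialylation
  percentages such as IGP24–IGP31, the with/without-bisecting ratios) are
  encoded exactly; the remaining entries are best-effort class-aggregate
  definitions chosen to be structurally coherent with their neighbours.
  The registry is a plain TSV (`inst/extdata/igp_trait_registry.tsv`) with
  a small expression dialect (`cls(fuc =, bis =, gal =, sia =, sia_min =)`)
  and is fully user-overridable; analyses that depend on exact formulas
  beyond the anchored set should supply their own registry.

Zero class denominators (an empty peak class in a real chromatogram)
produce missing values rather than errors; every downstream stage
tolerates missing cells. Peak GP5, dominated by an oligomannose species
that falls outside the grammar used here, carries an approximate
complex-type placeholder annotation and should be overridden when a better
assignment matters for a specific analysis.

## Quality control and phenotype preparation

Defaults follow common founder-cohort practice: samples are dropped below
97% genotype call rate, SNPs below 98% call rate, minor allele frequency
0.02, or an exact Hardy–Weinberg equilibrium p-value of 1e-10. All
"less than" removals are strict, so boundary values pass. HWE uses the
exact conditional test (enumeration of heterozygote counts given allele
counts) rather than the chi-squared approximation, because a 1e-10
threshold targets exactly the extreme tail where the approximation fails;
the implementation is checked against a brute-force enumeration oracle.

Phenotypes are prepared per trait: extreme outliers (more than three
interquartile ranges beyond the quartiles) are removed first, then the
trait is adjusted for covariates (sex, age, ancestry principal components
supplied as columns) by least squares, and the residuals are mapped onto
normal quantiles by the rank-based inverse-normal transform
`z = qnorm((rank - 0.5)/n)`. The offset 0.5/n and the tie rule
(deterministic stable-order ranking) are implementation choices — any
monotone transform of the input yields identical output, which is the
property association tests depend on. The resulting z-scores put SNP
effects in interpretable z-score units.

## Kinship, the polygenic model, and the mmscore test

Realized kinship is estimated from genome-wide dosages with
allele-frequency weighting,
\(K_{ij} = \frac{1}{L}\sum_l \frac{(g_{il}-2p_l)(g_{jl}-2p_l)}{4p_l(1-p_l)}\),
whose expectation is the pedigree kinship coefficient; `2K` is the genomic
relationship matrix. Missing genotypes are handled pairwise-complete and
monomorphic SNPs are skipped.

The polygenic null model places trait covariance
\(\Omega = 2K\sigma_g^2 + I\sigma_e^2\). One eigendecomposition of `2K`
(eigenvalues floored at 1e-10 to tolerate numerically indefinite
estimates) diagonalizes the problem, and the likelihood is profiled over
the single variance proportion by one-dimensional optimization, with the
OLS boundary checked explicitly. ML is the default, matching the lineage
of the tools this chain mirrors; REML is available behind a flag. When
many traits share one sample set, `kinship_eigen()` lets the
decomposition be reused across fits.

The association statistic is the family-aware score test: with the null
model's residuals \(r\) and the dosage centred by its \(\Omega\)-weighted
mean, \(\beta = (g^{*\top}\Omega^{-1}r)/(g^{*\top}\Omega^{-1}g^*)\) with
\(se = (g^{*\top}\Omega^{-1}g^*)^{-1/2}\) and \(\chi^2 = (\beta/se)^2\) on
1 df. The \(\Omega\)-weighted centring reduces to simple mean-centring
when \(\Omega \propto I\), where the statistic coincides with the
ordinary score test (both equivalences are tested, the former against a
dense-matrix oracle at 1e-8). Missing dosages are mean-imputed per SNP
and the non-missing count reported. Calibration is summarized by the
genomic-control factor \(\lambda = \mathrm{median}(\chi^2)/0.4549\);
a fully synthetic null study with 100 sibships of five, heritability 0.5
and 5,000 null SNPs keeps \(\lambda\) at or below 1.05
(`run_null_calibration()`, also the basis of `scripts/acceptance.R`).
Conditional re-scans append a top SNP's dosage to the covariates and
refit, so conditioning a SNP on itself (or a perfect proxy) annihilates
its statistic.

## Meta-analysis and multiplicity

Cohorts are pooled by fixed-effect inverse-variance weighting after
excluding SNPs with imputation quality below 0.3; Cochran's Q is computed
and reported but never used for filtering, as no heterogeneity-based
selection is part of the chain. The genome-wide significance threshold
divides 5e-8 by the effective number of independent traits: PCA of the
trait *correlation* matrix (correlation, because traits live on
heterogeneous percentage scales, making the effective count invariant to
rescaling) gives the smallest component count k reaching 99% cumulative
variance. The default divisor is k + 1, which reproduces the published
arithmetic in which 21 components at 99% variance produced a divisor of
22 and a threshold of 2.27e-9; because the "+1" is not derivable from
first principles, `divisor_mode = "k"` is provided and the choice is
surfaced in the decision object.

## Two-group glycome comparison

The small-sample knockout-style comparison reports per-trait group means,
their ratio, and a two-sided pooled-variance Student t-test (Welch behind
a flag), plus a global test: Hotelling's
\(T^2 = \frac{n_1 n_2}{n_1+n_2} d^\top S^+ d\) with the Moore–Penrose
pseudo-inverse of the pooled covariance. With 77 traits on 5 + 5 animals
the pooled covariance is necessarily singular; the pseudo-inverse
restricts the statistic to the observed span (flagged in the result),
which remains a valid fixed statistic because significance comes from an
empirical permutation distribution: group labels are permuted without
replacement (10,000 draws by default), and the p-value is the plain
proportion of permuted statistics at least as large as the observed one.
When the number of distinct labelings is small the test enumerates all of
them and the p-value is exact; a `(b+1)/(m+1)` estimator is available for
users who want a never-zero p. Traits can be residualized on covariates
beforehand (`residualize_traits()`), which keeps group means on the
measurement scale — deliberately *not* the rank-normal transform used for
association, since comparison tables must stay interpretable.

## Biomarker evaluation

Case-control discrimination uses maximum-likelihood logistic regression
(with explicit separation diagnostics), the Mann–Whitney AUC (ties count
0.5; equal to the trapezoidal area under the empirical ROC), and a DeLong
placement-value 95% CI for full-data AUCs. Robustness is assessed by
repeated stratified split-sample cross-validation: two thirds of cases
and of controls (sizes floored, preserving the case:control ratio) train
the model, the held-out third is scored, and the test AUC is recorded
over (by default) 1,000 repeats, summarized by the mean and a percentile
CI — percentile rather than DeLong, because the repeats, not asymptotics,
carry the uncertainty here. Rows with missing covariates are dropped
listwise with counts reported; duplicated predictor columns are dropped
with a warning rather than silently inflating the design.

## What the simulators emulate — and what they do not

Every stage is testable without external data because the package ships
generators for each input class: pedigrees with closed-form expected
kinship (sibships, nuclear families, singletons), founder genotypes in
HWE with Mendelian gene dropping, unit-variance polygenic traits where a
planted SNP explaining variance fraction v at frequency p has per-allele
effect \(\beta = \sqrt{v/2p(1-p)}\) (so that v = 0.172 at p = 0.30 gives
the reference effect 0.64 in z-score units), gamma-distributed UPLC peak
areas with a realistic human IgG layout, multivariate-normal two-group
glycomes, and a binormal case-control biomarker whose theoretical AUC is
\(\Phi(\Delta/\sqrt{2})\). Ages are uniform on 18–93 and sex is
Bernoulli(0.5), mirroring typical cohort ranges; these are cosmetic.

Deliberate simplifications: SNPs are independent (no linkage
disequilibrium), genotype missingness is uniform at random, glycome
traits are Gaussian rather than compositional in the group simulator, and
covariates are independent of case status (a matched design). Passing
tests therefore demonstrate correctness of the statistical machinery
under the assumed models — not robustness to LD structure, informative
missingness, or confounded covariates in real cohorts.

## Problem sizes and numerical choices

The test suite exercises the chain at sizes chosen to make Monte-Carlo
noise negligible relative to each assertion: the null-calibration study
uses 500 individuals and 5,000 SNPs; planted-effect recovery uses 100
replicates at n = 2,000; kinship convergence uses 20,000 SNPs; closed-form
AUC checks use 10,000+ observations. Key tolerances: dense-oracle
equivalence of the score test at 1e-8, HWE against enumeration at 1e-12,
pseudo-inverse tolerance 1e-10 relative to the largest singular value,
eigenvalue floor 1e-10 for the relationship matrix.

## Known limitations

* Derived-trait formulas beyond the anchored subset are best-effort; the
  registry is data, not code, precisely so it can be replaced.
* The two published recomputations that require supplementary data tables
  (the knockout-mouse glycome test and the SLE biomarker AUCs) run only
  when the user supplies the converted TSVs at the documented
  `inst/extdata` paths.
* The polygenic fit assumes a single homogeneous variance-component
  structure; X-chromosome models, interaction tests and genotype
  imputation are out of scope.
* Under the null, the ML heritability estimate piles up at the boundary
  (roughly half the replicates exactly zero for sibship designs) with a
  modest spread above it; this is a property of boundary ML estimation,
  not a defect, but users averaging heritabilities across traits should
  expect it.
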