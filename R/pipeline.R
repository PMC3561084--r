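#' Null-calibration study: family structure, polygenic trait, null SNPs
#'
#' Simulates a sibship-structured cohort with a purely polygenic trait (no
#' causal SNP), then runs the full association chain -- genotype QC,
#' covariate adjustment, rank-based inverse-normal transformation, genomic
#' kinship estimation, polygenic ML fit and the family-aware mmscore test
#' for every SNP -- and summarizes calibration by the genomic-control
#' inflation factor. A well-calibrated family-aware test keeps lambda
#' close to 1 despite the relatedness.
#'
#' @param n_families number of sibships (default 100).
#' @param sibship_size sibs per family (default 5).
#' @param h2 polygenic heritability of the simulated trait (default 0.5).
#' @param n_snps number of independent null SNPs (default 5000).
#' @param maf_range founder MAF range (default c(0.05, 0.5)).
#' @param seed integer seed controlling the whole run.
#' @return list with `lambda`, `assoc` (per-SNP results), `fit`
#'   (polygenic fit), `n_samples`, `n_snps_tested`.
#' @export
run_null_calibration <- function(n_families = 100, sibship_size = 5,
                                 h2 = 0.5, n_snps = 5000,
                                 maf_range = c(0.05, 0.5), seed = 1) {
  set.seed(seed)
  ped <- simulate_pedigree(n_families, "sibships", sibship_size)
  geno <- simulate_genotypes(ped$pedigree, n_snps, maf_range)
  obs <- ped$observed
  G <- geno$dosage[obs, , drop = FALSE]
  pheno <- simulate_trait(list(dosage = G), ped$kinship, causal_snp = NULL,
                          v = 0, h2 = h2,
                          covariate_effects = c(age = 0.01, sex = 0.2))
  sq <- sample_qc(G)
  G <- G[sq$keep, , drop = FALSE]
  pheno <- pheno[match(sq$keep, pheno$iid), ]
  kq <- snp_qc(G)
  G <- G[, kq$keep, drop = FALSE]
  z <- adjust_and_normalize(pheno$y, pheno[c("age", "sex")])
  K <- estimate_kinship(G)
  fit <- fit_polygenic(z$values, covariates = NULL, kinship = K)
  assoc <- mmscore_test(G, fit)
  list(lambda = genomic_control_lambda(assoc),
       assoc = assoc, fit = fit,
       n_samples = nrow(G), n_snps_tested = nrow(assoc))
}

#' End-to-end synthetic association pipeline with a planted SNP
#'
#' Exercises every stage through the on-disk formats: simulates a
#' pedigree-structured cohort with one causal SNP, writes and re-reads the
#' VCF, runs QC, adjustment and normalization, kinship estimation, the
#' polygenic fit and the mmscore scan, and meta-analyses the (single
#' cohort) result with the imputation-quality filter.
#'
#' @param n_families,sibship_size cohort structure.
#' @param n_snps number of SNPs (the causal SNP is placed mid-panel).
#' @param v variance explained by the planted SNP.
#' @param h2 polygenic heritability.
#' @param seed integer seed.
#' @param dir directory for intermediate files (default a tempdir).
#' @return list with `assoc` (meta table), `top_snp`, `causal_snp`,
#'   `planted_beta`, `lambda`, `files` (paths written).
#' @export
run_synthetic_pipeline <- function(n_families = 60, sibship_size = 4,
                                   n_snps = 300, v = 0.15, h2 = 0.3,
                                   seed = 1, dir = tempfile("glycopipe")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(n_families, "sibships", sibship_size)
  geno <- simulate_genotypes(ped$pedigree, n_snps)
  causal <- geno$map$snp[ceiling(n_snps / 2)]
  obs <- ped$observed
  gen_obs <- list(dosage = geno$dosage[obs, , drop = FALSE], map = geno$map)
  pheno <- simulate_trait(gen_obs, ped$kinship, causal_snp = causal, v = v,
                          h2 = h2, covariate_effects = c(age = 0.01, sex = 0.2))
  vcf_path <- file.path(dir, "cohort.vcf")
  fam_path <- file.path(dir, "cohort.fam")
  phe_path <- file.path(dir, "pheno.tsv")
  write_vcf(gen_obs, vcf_path)
  write_fam(ped$pedigree, fam_path)
  utils::write.table(pheno, phe_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  geno2 <- read_genotypes(vcf_path)
  pheno2 <- utils::read.delim(phe_path)
  stopifnot(identical(rownames(geno2$dosage), pheno2$iid))
  sq <- sample_qc(geno2)
  G <- geno2$dosage[sq$keep, , drop = FALSE]
  pheno2 <- pheno2[match(sq$keep, pheno2$iid), ]
  kq <- snp_qc(G)
  G <- G[, kq$keep, drop = FALSE]
  keep_out <- remove_outliers(pheno2$y)
  G <- G[keep_out, , drop = FALSE]
  pheno2 <- pheno2[keep_out, ]
  z <- adjust_and_normalize(pheno2$y, pheno2[c("age", "sex")])
  K <- estimate_kinship(G)
  fit <- fit_polygenic(z$values, covariates = NULL, kinship = K)
  assoc <- mmscore_test(list(dosage = G, map = geno2$map), fit)
  assoc_path <- file.path(dir, "assoc.tsv")
  write_assoc(assoc, assoc_path)
  meta <- meta_analyse(list(read_assoc(assoc_path)))
  list(assoc = meta,
       top_snp = meta$snp[which.min(meta$p)],
       causal_snp = causal,
       planted_beta = attr(pheno, "beta"),
       lambda = genomic_control_lambda(assoc),
       files = c(vcf = vcf_path, fam = fam_path, pheno = phe_path,
                 assoc = assoc_path))
}
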