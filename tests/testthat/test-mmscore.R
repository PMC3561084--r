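make_family_fit <- function(n_fam = 30, sibs = 4, h2 = 0.5, n_snps = 60,
                            seed = 40) {
  set.seed(seed)
  ped <- simulate_pedigree(n_fam, "sibships", sibs)
  geno <- simulate_genotypes(ped$pedigree, n_snps)
  G <- geno$dosage[ped$observed, , drop = FALSE]
  tr <- simulate_trait(list(dosage = G), ped$kinship, v = 0, h2 = h2)
  z <- adjust_and_normalize(tr$y, tr[c("age", "sex")])
  fit <- fit_polygenic(z$values, kinship = ped$kinship)
  list(G = G, fit = fit, K = ped$kinship, z = z$values)
}

test_that("mmscore agrees with the dense-matrix oracle to 1e-8", {
  env <- make_family_fit()
  omega <- 2 * env$K * env$fit$sigma_g2 + diag(env$fit$sigma_e2, env$fit$n)
  res <- mmscore_test(env$G, env$fit)
  for (j in c(1, 17, 42)) {
    oracle <- mmscore_dense_oracle(env$G[, j], env$fit$r, omega)
    expect_equal(res$beta[j], oracle$beta, tolerance = 1e-8)
    expect_equal(res$se[j], oracle$se, tolerance = 1e-8)
    expect_equal(res$chi2[j], oracle$chi2, tolerance = 1e-8)
  }
  expect_equal(res$chi2, (res$beta / res$se)^2, tolerance = 1e-10)
})

test_that("with no polygenic variance mmscore equals the OLS score test", {
  set.seed(41)
  n <- 200
  y <- rnorm(n)
  G <- matrix(rbinom(n * 30, 2, 0.3), n, 30,
              dimnames = list(sprintf("i%d", 1:n), sprintf("s%d", 1:30)))
  fit <- fit_polygenic(y, kinship = matrix(0, n, n))
  expect_equal(fit$sigma_g2, 0)
  res <- mmscore_test(G, fit)
  r <- y - mean(y)
  ols_chi2 <- vapply(1:30, function(j) {
    g <- G[, j] - mean(G[, j])
    sum(g * r)^2 / (sum(g^2) * fit$sigma_e2)
  }, numeric(1))
  expect_equal(res$chi2, ols_chi2, tolerance = 1e-8)
})

test_that("statistics are invariant under consistent sample reordering", {
  env <- make_family_fit(seed = 42)
  res <- mmscore_test(env$G, env$fit)
  perm <- sample(nrow(env$G))
  fit_p <- fit_polygenic(env$z[perm], kinship = env$K[perm, perm])
  res_p <- mmscore_test(env$G[perm, ], fit_p)
  expect_equal(res_p$chi2, res$chi2, tolerance = 1e-6)
  expect_equal(res_p$beta, res$beta, tolerance = 1e-6)
})

test_that("effect sign follows the trait-dosage covariance when Omega is spherical", {
  set.seed(43)
  n <- 300
  g <- rbinom(n, 2, 0.4)
  y <- 0.3 * g + rnorm(n)
  fit <- fit_polygenic(y, kinship = matrix(0, n, n))
  res <- mmscore_test(matrix(g, ncol = 1, dimnames = list(NULL, "g")), fit)
  expect_equal(sign(res$beta), sign(cov(y, g)))
  expect_gt(res$chi2, 1)
})

test_that("monomorphic SNPs are flagged untestable and missing dosages are mean-imputed", {
  env <- make_family_fit(seed = 44, n_snps = 10)
  G <- env$G
  G[, 1] <- 1L
  G[1:5, 2] <- NA
  res <- mmscore_test(G, env$fit)
  expect_true(is.na(res$beta[1]))
  expect_true(is.na(res$p[1]))
  expect_equal(res$n[2], nrow(G) - 5L)
  expect_false(is.na(res$p[2]))
})

test_that("null p-values are uniform and type-I error is nominal under family structure", {
  set.seed(45)
  ped <- simulate_pedigree(80, "sibships", 4)
  geno <- simulate_genotypes(ped$pedigree, 6000)
  G <- geno$dosage[ped$observed, ]
  tr <- simulate_trait(list(dosage = G), ped$kinship, v = 0, h2 = 0.5)
  z <- adjust_and_normalize(tr$y, tr[c("age", "sex")])
  fit <- fit_polygenic(z$values, kinship = estimate_kinship(G))
  res <- mmscore_test(G, fit)
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
  rej <- mean(res$p < 0.05)
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})

test_that("variance explained follows 2pq beta^2 and matches the printed example", {
  expect_equal(round(100 * variance_explained(0.64, 0.30)), 17)
  expect_equal(variance_explained(0, 0.3), 0)
  expect_equal(variance_explained(1, 0.5), 0.5)
})

test_that("genomic-control lambda is 1 at the null median and scale-equivariant", {
  med <- qchisq(0.5, 1)
  x <- c(rep(med - 0.1, 50), med, rep(med + 0.1, 50))
  expect_equal(genomic_control_lambda(x), 1, tolerance = 1e-6)
  set.seed(46)
  chi <- rchisq(5000, 1)
  expect_equal(genomic_control_lambda(2 * chi), 2 * genomic_control_lambda(chi))
})

test_that("conditioning on a SNP annihilates its own and a perfect proxy's signal", {
  set.seed(47)
  ped <- simulate_pedigree(50, "sibships", 4)
  geno <- simulate_genotypes(ped$pedigree, 30)
  G <- geno$dosage[ped$observed, ]
  G <- cbind(G, proxy = G[, 5])
  tr <- simulate_trait(list(dosage = G), ped$kinship, causal_snp = 5L,
                       v = 0.15, h2 = 0.3)
  z <- adjust_and_normalize(tr$y, tr[c("age", "sex")])
  cond <- conditional_scan(G, z$values, top_snp = 5L, kinship = ped$kinship)
  expect_lt(cond$chi2[5], 1e-6)
  expect_lt(cond$chi2[colnames(G) == "proxy"], 1e-6)
  # an independent SNP keeps a comparable statistic
  fit <- fit_polygenic(z$values, kinship = ped$kinship)
  uncond <- mmscore_test(G, fit)
  expect_lt(abs(cond$chi2[20] - uncond$chi2[20]), 3)
  expect_error(conditional_scan(cbind(G, mono = 0L), z$values, top_snp = "mono",
                                kinship = ped$kinship), "monomorphic")
})
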