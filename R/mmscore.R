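#' Family-aware mmscore association test
#'
#' Score test for additive single-SNP association in samples with
#' relatedness. Using the polygenic null fit's residual vector `r` and
#' covariance `Omega = 2 K sigma_g^2 + I sigma_e^2`, each SNP dosage `g`
#' is centred by its Omega-weighted mean,
#' `g* = g - (1' Omega^-1 g) / (1' Omega^-1 1)`, and
#' `beta = (g*' Omega^-1 r) / (g*' Omega^-1 g*)`,
#' `se = (g*' Omega^-1 g*)^{-1/2}`, `chi2 = (beta / se)^2` referred to
#' chi-squared on 1 df. When `Omega` is proportional to the identity this
#' reduces to the ordinary (unrelated-sample) score test.
#'
#' Missing dosages are mean-imputed per SNP (score tests need complete
#' vectors); the non-missing count is reported in `n`. Monomorphic SNPs
#' are flagged untestable (`NA` statistics).
#'
#' @param genotypes dosage matrix (samples x SNPs), dosage vector, or list
#'   with `dosage` (+ optional `map` carrying `snp`, `r2` columns).
#' @param fit a [fit_polygenic()] result on the same samples, same order.
#' @return data frame of class `assoc_result`: `snp`, `n`, `maf`, `beta`,
#'   `se`, `chi2`, `p` (+ `r2_imputation` when available).
#' @export
mmscore_test <- function(genotypes, fit) {
  map <- NULL
  G <- if (is.list(genotypes) && !is.null(genotypes$dosage)) {
    map <- genotypes$map
    genotypes$dosage
  } else genotypes
  if (is.null(dim(G))) G <- matrix(G, ncol = 1L, dimnames = list(names(G), "g"))
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  stopifnot(nrow(G) == fit$n)
  n_obs <- colSums(!is.na(G))
  p_alt <- colMeans(G, na.rm = TRUE) / 2
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) {
      gj <- G[, j]
      gj[is.na(gj)] <- 2 * p_alt[j]
      G[, j] <- gj
    }
  }
  maf <- pmin(p_alt, 1 - p_alt)
  vr <- apply(G, 2L, stats::var)
  testable <- is.finite(vr) & vr > 0
  Gt <- omega_whiten(fit, G)
  rt <- drop(omega_whiten(fit, fit$r))
  ot <- drop(omega_whiten(fit, rep(1, fit$n)))
  s11 <- sum(ot^2)
  s1r <- sum(ot * rt)
  a <- drop(crossprod(ot, Gt))                 # 1' Omega^-1 g per SNP
  gg <- colSums(Gt^2) - a^2 / s11              # g*' Omega^-1 g*
  gr <- drop(crossprod(rt, Gt)) - a * s1r / s11
  testable <- testable & gg > 1e-12
  gg[!testable] <- NA_real_
  beta <- gr / gg
  se <- 1 / sqrt(gg)
  chi2 <- gr^2 / gg
  out <- data.frame(
    snp = if (!is.null(colnames(G))) colnames(G) else sprintf("snp%d", seq_len(ncol(G))),
    n = n_obs, maf = maf, beta = beta, se = se, chi2 = chi2,
    p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(map) && "r2" %in% names(map))
    out$r2_imputation <- map$r2[match(out$snp, map$snp)]
  class(out) <- c("assoc_result", class(out))
  out
}

#' Variance explained by an additive SNP effect
#'
#' On a unit-variance trait scale, a per-allele effect `beta` at allele
#' frequency `maf` explains `2 maf (1 - maf) beta^2` of the trait variance
#' under HWE additivity.
#'
#' @param beta per-allele effect (z-score units).
#' @param maf allele frequency.
#' @return fraction of variance explained.
#' @examples
#' variance_explained(0.64, 0.30)  # ~0.172, i.e. 17%
#' @export
variance_explained <- function(beta, maf) {
  2 * maf * (1 - maf) * beta^2
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / 0.4549`, the ratio of the observed median test
#' statistic to the median of chi-squared(1). Values near 1 indicate a
#' calibrated test; inflation from unmodelled structure pushes lambda
#' above 1.
#'
#' @param chi2 vector of 1-df association statistics (or an
#'   `assoc_result`).
#' @return lambda.
#' @export
genomic_control_lambda <- function(chi2) {
  if (is.data.frame(chi2)) chi2 <- chi2$chi2
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) < 100)
    warning("lambda estimated from fewer than 100 statistics")
  stats::median(chi2) / stats::qchisq(0.5, df = 1)
}

#' Conditional association re-scan
#'
#' Re-runs the polygenic fit and mmscore test with the dosage of a top SNP
#' appended to the covariates, as used to test whether an association peak
#' carries secondary signals.
#'
#' @param genotypes dosage matrix or list with `dosage` (the SNPs to
#'   re-test).
#' @param y trait (z-scores).
#' @param covariates optional covariate matrix.
#' @param top_snp name or index of the SNP to condition on.
#' @param kinship kinship matrix or [kinship_eigen()].
#' @return an `assoc_result` for all SNPs, conditional on `top_snp`.
#' @export
conditional_scan <- function(genotypes, y, covariates = NULL, top_snp,
                             kinship) {
  G <- if (is.list(genotypes)) genotypes$dosage else genotypes
  g_top <- G[, top_snp]
  if (stats::var(g_top, na.rm = TRUE) == 0) stop("top SNP is monomorphic")
  g_top[is.na(g_top)] <- mean(g_top, na.rm = TRUE)
  covariates2 <- cbind(covariates, top_snp_dosage = g_top)
  fit <- fit_polygenic(y, covariates2, kinship)
  mmscore_test(genotypes, fit)
}
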