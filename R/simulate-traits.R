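#' Simulate a polygenic quantitative trait with an optional planted SNP
#'
#' The trait is built on a unit-variance scale so that a planted per-allele
#' effect is directly comparable to effect sizes reported in z-score units:
#' for a causal SNP at allele frequency p explaining a fraction `v` of the
#' variance under additivity and HWE, the per-allele effect is
#' `beta = sqrt(v / (2 p (1 - p)))`. A polygenic component with covariance
#' `2 K h2` (K the expected kinship) and an independent residual scaled to
#' `1 - v - h2` complete the genetic model; optional fixed covariate effects
#' (age, sex) are added on top and are meant to be removed again by
#' [adjust_and_normalize()].
#'
#' @param genotypes result of [simulate_genotypes()] (or a dosage matrix).
#' @param kinship expected kinship matrix over the simulated individuals
#'   (rows of the dosage matrix); used to draw the polygenic component.
#' @param causal_snp column index or name of the causal SNP, or `NULL`.
#' @param v fraction of trait variance explained by the causal SNP.
#' @param h2 narrow-sense heritability of the polygenic background.
#' @param covariate_effects named numeric, e.g. `c(age = 0.01, sex = 0.2)`;
#'   effects are per year of age and for sex = 2 vs 1.
#' @param seed optional integer seed.
#' @return data frame `iid`, `y`, `age`, `sex` with attributes `beta`
#'   (planted per-allele effect) and `causal_snp`.
#' @export
simulate_trait <- function(genotypes, kinship, causal_snp = NULL, v = 0,
                           h2 = 0, covariate_effects = c(age = 0, sex = 0),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- if (is.list(genotypes)) genotypes$dosage else genotypes
  n <- nrow(G)
  if (v + h2 > 1) stop("v + h2 must not exceed 1")
  ids <- rownames(G)
  stopifnot(identical(rownames(kinship), ids))
  y <- numeric(n)
  beta <- 0
  if (!is.null(causal_snp) && v > 0) {
    g <- G[, causal_snp]
    p <- mean(g, na.rm = TRUE) / 2
    if (p <= 0 || p >= 1) stop("causal SNP is monomorphic")
    beta <- sqrt(v / (2 * p * (1 - p)))
    g[is.na(g)] <- 2 * p
    y <- y + beta * (g - 2 * p)
  }
  if (h2 > 0) {
    # chol of 2K h2; small jitter guards numerically semidefinite pedigree K
    L <- chol(2 * kinship * h2 + diag(1e-8, n))
    y <- y + drop(crossprod(L, stats::rnorm(n)))
  }
  y <- y + stats::rnorm(n, sd = sqrt(max(1 - v - h2, 0)))
  age <- stats::runif(n, 18, 93)
  sex <- stats::rbinom(n, 1L, 0.5) + 1L
  eff <- c(age = 0, sex = 0)
  eff[names(covariate_effects)] <- covariate_effects
  y <- y + eff[["age"]] * age + eff[["sex"]] * (sex - 1L)
  out <- data.frame(iid = ids, y = y, age = age, sex = sex,
                    stringsAsFactors = FALSE)
  attr(out, "beta") <- beta
  attr(out, "causal_snp") <- causal_snp
  out
}

#' Simulate glycome peak profiles
#'
#' Draws per-sample raw UPLC peak areas from independent gamma
#' distributions whose means follow a typical human IgG glycome layout
#' (dominant agalactosylated and monogalactosylated core-fucosylated peaks,
#' smaller sialylated peaks), then leaves them un-normalized so that the
#' relative-area normalization step is exercised downstream.
#'
#' @param n number of samples.
#' @param mean_profile optional length-24 positive vector of mean areas.
#' @param cv coefficient of variation of each peak area.
#' @param seed optional integer seed.
#' @return matrix n x 24 of raw areas with columns GP1..GP24.
#' @export
simulate_glycome_profiles <- function(n, mean_profile = NULL, cv = 0.25,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_profile))
    mean_profile <- c(0.2, 0.7, 0.5, 18, 0.3, 3.5, 0.6, 16, 8.5, 4.5,
                      0.7, 1.0, 0.5, 12, 1.5, 2.5, 1.5, 12, 2.0, 0.5,
                      1.5, 0.5, 10, 1.0)
  stopifnot(length(mean_profile) == 24L, all(mean_profile > 0))
  shape <- 1 / cv^2
  areas <- matrix(stats::rgamma(n * 24L, shape = shape,
                                rate = shape / rep(mean_profile, each = n)),
                  nrow = n)
  dimnames(areas) <- list(sprintf("S%04d", seq_len(n)), sprintf("GP%d", 1:24))
  areas
}
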