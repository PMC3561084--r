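#' Estimate realized pairwise kinship from SNP dosages
#'
#' Allele-frequency-weighted genomic kinship: for SNP l with ALT frequency
#' p_l, the contribution of a pair (i, j) is
#' `(g_il - 2 p_l)(g_jl - 2 p_l) / (4 p_l (1 - p_l))`, averaged over SNPs
#' (pairwise-complete when genotypes are missing). The expectation of
#' K_ij equals the pedigree kinship coefficient (0.5 self, 0.25 full sibs),
#' so `2K` plays the role of the genomic relationship matrix in the
#' polygenic model. The same cross-product form serves the diagonal, whose
#' expectation `0.5 * (1 + F_i)` inflates self-kinship under inbreeding;
#' identical genotype rows therefore yield `K_ij = K_ii` exactly.
#'
#' @param genotypes dosage matrix (samples x SNPs) or list with `dosage`.
#' @param min_snps warn below this SNP count (default 100).
#' @return symmetric kinship matrix with sample ids as dimnames.
#' @export
estimate_kinship <- function(genotypes, min_snps = 100) {
  G <- if (is.list(genotypes)) genotypes$dosage else genotypes
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  p <- colMeans(G, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic SNP(s) skipped in kinship estimation")
    G <- G[, poly, drop = FALSE]
    p <- p[poly]
  }
  L <- ncol(G)
  if (L < min_snps)
    warning("kinship estimated from only ", L, " SNPs; expect noisy estimates")
  w <- sqrt(4 * p * (1 - p))
  Z <- sweep(G, 2L, 2 * p)
  Zs <- sweep(Z, 2L, w, "/")
  miss <- is.na(Zs)
  if (any(miss)) {
    Zs[miss] <- 0
    obs <- (!miss) * 1
    counts <- tcrossprod(obs)
    K <- tcrossprod(Zs) / counts
  } else {
    K <- tcrossprod(Zs) / L
  }
  dimnames(K) <- list(rownames(G), rownames(G))
  (K + t(K)) / 2
}

#' Eigendecomposition of the genomic relationship matrix 2K
#'
#' One decomposition of `2K` serves every downstream variance-component
#' fit and score test; reuse it when fitting many traits on the same
#' samples. Eigenvalues are floored at 1e-10 to tolerate numerically
#' indefinite kinship estimates.
#'
#' @param K kinship matrix.
#' @return list with `vectors` (U), `values` (floored eigenvalues of 2K)
#'   and `ids`.
#' @export
kinship_eigen <- function(K) {
  K <- (K + t(K)) / 2
  ev <- eigen(2 * K, symmetric = TRUE)
  list(vectors = ev$vectors, values = pmax(ev$values, 1e-10),
       ids = rownames(K))
}
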