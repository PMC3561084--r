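# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration / dense algebra) kept separate from the code
# paths it checks.

# Exact HWE p by brute-force enumeration of every heterozygote count with
# the observed allele counts, using multinomial coefficients directly.
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab
  if (na == 0 || na == 2 * n) return(1)
  hets <- seq(min(na, 2 * n - na) %% 2, min(na, 2 * n - na), by = 2)
  unnorm <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - aa - h
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
          h * log(2))
  }, numeric(1))
  prob <- unnorm / sum(unnorm)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# mmscore statistics by dense matrix algebra: explicit Omega inverse.
mmscore_dense_oracle <- function(g, r, omega) {
  oi <- solve(omega)
  one <- rep(1, length(g))
  gs <- g - drop(one %*% oi %*% g) / drop(one %*% oi %*% one) * one
  den <- drop(gs %*% oi %*% gs)
  beta <- drop(gs %*% oi %*% r) / den
  list(beta = beta, se = 1 / sqrt(den), chi2 = beta^2 * den)
}

# Trapezoidal area under the empirical ROC curve.
roc_trapezoid_oracle <- function(scores, status) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[status == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[status == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Pooled-variance two-sample t statistic, closed form.
pooled_t_oracle <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Two-group matrices with exact given means (used for printed-table checks).
groups_with_means <- function(means_a, means_b, n = 5, spread = 0.1) {
  dev <- seq(-spread, spread, length.out = n) - mean(seq(-spread, spread, length.out = n))
  a <- outer(dev, rep(1, length(means_a))) + outer(rep(1, n), means_a)
  b <- outer(rev(dev), rep(1, length(means_b))) + outer(rep(1, n), means_b)
  colnames(a) <- colnames(b) <- names(means_a)
  list(a = a, b = b)
}
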