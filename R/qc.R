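#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the allele counts, the probability of every
#' possible heterozygote count is enumerated under the hypergeometric
#' sampling distribution implied by HWE, and the p-value sums the
#' probabilities of all outcomes no more probable than the observed one.
#' The exact test is used (rather than the chi-squared approximation)
#' because QC thresholds of the order of 1e-10 target extreme departures
#' where the approximation is unreliable.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major hom, het, minor hom).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_test(40, 20, 40)   # strong het deficit
#' hwe_exact_test(25, 50, 25)   # HWE proportions
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("at least one genotype required")
  na <- 2 * n_aa + n_ab   # count of A alleles
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  rare <- min(na, nb)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(n_ab = h | allele counts) up to a common constant:
  #   n! / (n_aa! n_ab! n_bb!) * 2^n_ab  with n_aa=(na-h)/2, n_bb=(nb-h)/2
  logp <- vapply(hets, function(h) {
    h * log(2) - lgamma((na - h) / 2 + 1) - lgamma(h + 1) -
      lgamma((nb - h) / 2 + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- prob[match(n_ab, hets)]
  p <- sum(prob[prob <= obs * (1 + 1e-12)])
  min(p, 1)
}

#' Sample-level genotype call-rate QC
#'
#' Samples whose genotype call rate is *less than* the threshold are
#' removed; a call rate exactly at the threshold is kept.
#'
#' @param genotypes dosage matrix (samples x SNPs, `NA` = missing) or a
#'   list with a `dosage` element.
#' @param min_call_rate minimum fraction of non-missing genotypes
#'   (default 0.97).
#' @return list with `keep` (ids kept) and `report` (per-sample data frame
#'   `iid`, `call_rate`, `kept`).
#' @export
sample_qc <- function(genotypes, min_call_rate = 0.97) {
  G <- if (is.list(genotypes)) genotypes$dosage else genotypes
  cr <- rowMeans(!is.na(G))
  kept <- cr >= min_call_rate
  if (!any(kept)) stop("sample QC removed every sample")
  list(keep = rownames(G)[kept],
       report = data.frame(iid = rownames(G), call_rate = cr, kept = kept,
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' SNP-level QC: call rate, minor allele frequency, HWE
#'
#' A SNP is kept iff its call rate is at least `min_call_rate`, its minor
#' allele frequency at least `min_maf` and its HWE exact-test p-value at
#' least `min_hwe_p` (all "less than" removals are strict, so boundary
#' values pass). HWE is tested on hard calls; non-integer dosages are
#' rounded for the genotype counts.
#'
#' @inheritParams sample_qc
#' @param min_call_rate minimum SNP call rate (default 0.98).
#' @param min_maf minimum minor allele frequency (default 0.02).
#' @param min_hwe_p minimum HWE exact p (default 1e-10).
#' @return list with `keep` (SNP ids kept) and `report` data frame
#'   (`snp`, `call_rate`, `maf`, `hwe_p`, `kept`).
#' @export
snp_qc <- function(genotypes, min_call_rate = 0.98, min_maf = 0.02,
                   min_hwe_p = 1e-10) {
  G <- if (is.list(genotypes)) genotypes$dosage else genotypes
  cr <- colMeans(!is.na(G))
  p_alt <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- round(G[, j])
    g <- g[!is.na(g)]
    if (length(g) == 0L) return(1)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  kept <- cr >= min_call_rate & maf >= min_maf & hwe >= min_hwe_p
  list(keep = colnames(G)[kept],
       report = data.frame(snp = colnames(G), call_rate = cr, maf = maf,
                           hwe_p = hwe, kept = kept, row.names = NULL,
                           stringsAsFactors = FALSE))
}

#' Flag extreme phenotype outliers by interquartile fences
#'
#' A value is removed when it lies more than three interquartile ranges
#' beyond the 25th or 75th percentile ("more than" is strict: a value
#' exactly on the fence is kept). Missing values are left in place.
#'
#' @param values numeric vector (>= 4 non-missing values required).
#' @return logical keep mask of the same length (`TRUE` for `NA` input).
#' @export
remove_outliers <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- rep(TRUE, length(values))
  keep[ok] <- values[ok] >= q[1] - 3 * iqr & values[ok] <= q[2] + 3 * iqr
  keep
}
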