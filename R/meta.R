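#' Inverse-variance weighted fixed-effect meta-analysis
#'
#' Pools per-cohort effect estimates with weights `w_i = se_i^-2`:
#' pooled `beta = sum(w beta) / sum(w)`, pooled `se = sum(w)^-0.5`, p-value
#' two-sided normal. Cochran's Q is computed for description only; no
#' heterogeneity-based filtering is applied.
#'
#' @param beta numeric vector of per-cohort effects (one SNP).
#' @param se matching standard errors (> 0).
#' @return list `beta`, `se`, `p`, `q` (Cochran), `n_cohorts`.
#' @examples
#' ivw_meta(c(0.64, 0.64), c(0.04, 0.04))  # se shrinks by sqrt(2)
#' @export
ivw_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1L)
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s,
       p = 2 * stats::pnorm(-abs(b / s)),
       q = sum(w * (beta - b)^2),
       n_cohorts = length(beta))
}

#' Meta-analyse per-cohort association tables
#'
#' @param tables list of `assoc_result` data frames (one per cohort) with
#'   columns `snp`, `beta`, `se` (+ optional `n`, `r2_imputation`).
#' @param min_r2 SNPs with imputation quality below this are excluded per
#'   cohort before pooling (see [imputation_filter()]); `NULL` disables.
#' @return data frame `snp`, `beta`, `se`, `p`, `q`, `n_cohorts`, `n`.
#' @export
meta_analyse <- function(tables, min_r2 = 0.3) {
  stopifnot(length(tables) >= 1L)
  if (!is.null(min_r2)) tables <- lapply(tables, imputation_filter, min_r2 = min_r2)
  tables <- lapply(tables, function(t) t[is.finite(t$beta) & is.finite(t$se), ])
  snps <- sort(unique(unlist(lapply(tables, `[[`, "snp"))))
  rows <- lapply(snps, function(s) {
    b <- unlist(lapply(tables, function(t) t$beta[t$snp == s]))
    e <- unlist(lapply(tables, function(t) t$se[t$snp == s]))
    n <- sum(unlist(lapply(tables, function(t) t$n[t$snp == s])))
    m <- ivw_meta(b, e)
    data.frame(snp = s, beta = m$beta, se = m$se, p = m$p, q = m$q,
               n_cohorts = m$n_cohorts, n = if (length(n)) n else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("meta_result", class(out))
  out
}

#' Filter association results on imputation quality
#'
#' SNPs with imputation R-squared strictly below `min_r2` are excluded;
#' `r2 = min_r2` is kept. Results without an imputation-quality column (or
#' with missing values) pass with a warning.
#'
#' @param results `assoc_result` data frame.
#' @param min_r2 threshold (default 0.3).
#' @return filtered data frame.
#' @export
imputation_filter <- function(results, min_r2 = 0.3) {
  r2 <- results$r2_imputation
  if (is.null(r2)) {
    warning("no imputation-quality column; all SNPs kept")
    return(results)
  }
  if (anyNA(r2)) warning(sum(is.na(r2)), " SNP(s) without imputation R2 kept")
  keep <- is.na(r2) | r2 >= min_r2
  results[keep, , drop = FALSE]
}

#' Effective-number-of-traits significance threshold
#'
#' Principal component analysis of the trait *correlation* matrix
#' determines how many independent traits the glycome panel effectively
#' contains: `k` is the smallest number of components whose cumulative
#' explained variance reaches `var_target`. The genome-wide significance
#' base threshold is divided by `k` or `k + 1` depending on
#' `divisor_mode`; the default `"k_plus_one"` reproduces the published
#' arithmetic in which 21 components at 99% variance yielded a divisor of
#' 22 (5e-8 / 22 = 2.27e-9).
#'
#' @param traits samples x traits numeric matrix.
#' @param var_target cumulative variance target (default 0.99).
#' @param base base genome-wide threshold (default 5e-8).
#' @param divisor_mode `"k_plus_one"` (default) or `"k"`.
#' @return object of class `multiplicity_decision` with `n_traits`, `k`,
#'   `divisor`, `threshold`, `cumvar`.
#' @export
effective_traits_threshold <- function(traits, var_target = 0.99, base = 5e-8,
                                       divisor_mode = c("k_plus_one", "k")) {
  divisor_mode <- match.arg(divisor_mode)
  traits <- as.matrix(traits)
  stopifnot(ncol(traits) >= 2L)
  sds <- apply(traits, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sds) | sds == 0
  if (any(constant)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(traits)[constant], collapse = ", "))
    traits <- traits[, !constant, drop = FALSE]
  }
  cm <- stats::cor(traits, use = "pairwise.complete.obs")
  cm[is.na(cm)] <- 0
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cumvar <- cumsum(ev) / sum(ev)
  k <- which(cumvar >= var_target)[1L]
  divisor <- if (divisor_mode == "k") k else k + 1L
  structure(list(n_traits = ncol(traits), k = k, divisor = divisor,
                 divisor_mode = divisor_mode, threshold = base / divisor,
                 cumvar = cumvar),
            class = "multiplicity_decision")
}

#' @export
print.multiplicity_decision <- function(x, ...) {
  cat(sprintf("%d traits: %d principal components reach %.0f%% variance\n",
              x$n_traits, x$k, 100 * x$cumvar[x$k]))
  cat(sprintf("  divisor %d (%s) -> genome-wide threshold %.3g\n",
              x$divisor, x$divisor_mode, x$threshold))
  invisible(x)
}

#' Classify meta-analysis hits into significance tiers
#'
#' Tiers: `genome_wide_significant` (p below the multiplicity-adjusted
#' threshold), `strongly_suggestive` (up to 5e-8), `suggestive` (below
#' 1e-5), otherwise `ns`.
#'
#' @param p p-values (or a `meta_result` data frame).
#' @param decision a `multiplicity_decision`.
#' @param base upper bound of the strongly-suggestive tier (default 5e-8).
#' @param suggestive upper bound of the suggestive tier (default 1e-5).
#' @return factor of tiers (or the input data frame with a `tier` column).
#' @export
classify_hits <- function(p, decision, base = 5e-8, suggestive = 1e-5) {
  df <- NULL
  if (is.data.frame(p)) { df <- p; p <- df$p }
  tier <- ifelse(p < decision$threshold, "genome_wide_significant",
          ifelse(p <= base, "strongly_suggestive",
          ifelse(p < suggestive, "suggestive", "ns")))
  tier <- factor(tier, levels = c("genome_wide_significant",
                                  "strongly_suggestive", "suggestive", "ns"))
  if (is.null(df)) return(tier)
  df$tier <- tier
  df
}
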