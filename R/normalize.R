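#' Covariate adjustment and rank-based inverse-normal transformation
#'
#' Regresses the trait on the supplied covariates by least squares, then
#' maps the residual ranks onto standard normal quantiles:
#' `z_i = qnorm((r_i - 0.5) / n)` with `r_i` the residual rank. The result
#' is the z-score phenotype used for association testing; by construction
#' its empirical distribution matches normal quantiles, its mean is ~0 and
#' its sd ~1. Ties are broken deterministically by stable input order.
#'
#' @param y numeric trait vector.
#' @param covariates optional data frame / matrix of covariates (e.g. sex,
#'   age, ancestry principal components). An intercept is always added.
#' @return object of class `zscore_trait`: list with `values` (z-scores,
#'   `NA` where `y` or a covariate was missing), `covariates_used`,
#'   `n_used`, and the fitted `lm` coefficients.
#' @details Rank-deficient covariate sets raise an error naming the
#'   collinear columns. Observations with missing trait or covariates are
#'   returned as `NA` and excluded from the fit.
#' @export
adjust_and_normalize <- function(y, covariates = NULL) {
  n_all <- length(y)
  if (is.null(covariates)) {
    X <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n_all)
    mf <- stats::model.frame(~ ., data = covariates, na.action = stats::na.pass)
    X <- stats::model.matrix(~ ., data = mf)
  }
  use <- !is.na(y) & stats::complete.cases(X)
  Xu <- X[use, , drop = FALSE]
  qrX <- qr(Xu)
  if (qrX$rank < ncol(Xu)) {
    aliased <- colnames(Xu)[qrX$pivot[(qrX$rank + 1):ncol(Xu)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- qr.resid(qrX, y[use])
  n <- length(res)
  z <- stats::qnorm((rank(res, ties.method = "first") - 0.5) / n)
  values <- rep(NA_real_, n_all)
  values[use] <- z
  structure(list(values = values,
                 covariates_used = colnames(X),
                 n_used = n,
                 coefficients = qr.coef(qrX, y[use])),
            class = "zscore_trait")
}

#' @export
print.zscore_trait <- function(x, ...) {
  cat(sprintf("z-score trait: n = %d (of %d), covariates: %s\n", x$n_used,
              length(x$values), paste(x$covariates_used, collapse = ", ")))
  invisible(x)
}
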