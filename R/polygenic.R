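#' Fit the polygenic null model by maximum likelihood
#'
#' Mixed model `y = X b + u + e` with `Var(u) = 2 K sigma_g^2` and
#' `Var(e) = I sigma_e^2`, so the phenotypic covariance is
#' `Omega = 2 K sigma_g^2 + I sigma_e^2`. On the eigenbasis of `2K`
#' (`2K = U L U'`), Omega is diagonal, and the likelihood profiles over a
#' single variance ratio: with total variance `s2` and proportion `h`,
#' `d_i = h * lambda_i + (1 - h)` and `Omega = s2 * U diag(d) U'`. The ML
#' solution maximizes the profile log-likelihood over `h` in [0, 1) by
#' one-dimensional optimization, with the boundary `h = 0` (ordinary least
#' squares) checked explicitly.
#'
#' @param y numeric trait (ideally z-scores from [adjust_and_normalize()]).
#' @param covariates optional matrix / data frame of fixed effects (an
#'   intercept is always included).
#' @param kinship kinship matrix `K`, or a precomputed [kinship_eigen()].
#' @param reml use REML instead of ML for the variance components.
#' @return object of class `polygenic_fit`: fixed-effect estimates,
#'   `sigma_g2`, `sigma_e2`, heritability `h2` (scaled by the mean
#'   eigenvalue of 2K so that outbred samples give `h2 ~ sigma_g2 /
#'   (sigma_g2 + sigma_e2)`), `loglik`, raw-scale residuals `r`, and the
#'   eigen representation needed to apply `Omega^{-1}` downstream.
#' @export
fit_polygenic <- function(y, covariates = NULL, kinship, reml = FALSE) {
  n <- length(y)
  if (anyNA(y)) stop("missing trait values; subset to complete cases first")
  keig <- if (is.list(kinship) && !is.null(kinship$vectors)) kinship
  else kinship_eigen(as.matrix(kinship))
  stopifnot(length(keig$values) == n)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  U <- keig$vectors
  lam <- keig$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)
  neg2ll <- function(h) {
    d <- h * lam + (1 - h)
    w <- 1 / d
    XtWX <- crossprod(Xt, Xt * w)
    XtWy <- crossprod(Xt, yt * w)
    b <- solve(XtWX, XtWy)
    rss <- sum(w * (yt - Xt %*% b)^2)
    if (reml) {
      s2 <- rss / (n - p)
      (n - p) * log(s2) + sum(log(d)) + determinant(XtWX)$modulus[1] +
        (n - p) * (1 + log(2 * pi))
    } else {
      s2 <- rss / n
      n * log(s2) + sum(log(d)) + n * (1 + log(2 * pi))
    }
  }
  if (max(lam) < 1e-8) {
    h_opt <- 0     # degenerate kinship: model collapses to OLS
  } else {
    opt <- stats::optimize(neg2ll, c(0, 0.9999), tol = 1e-8)
    h_opt <- if (neg2ll(0) <= opt$objective) 0 else opt$minimum
  }
  d <- h_opt * lam + (1 - h_opt)
  w <- 1 / d
  b <- solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
  rss <- sum(w * (yt - Xt %*% b)^2)
  s2 <- if (reml) rss / (n - p) else rss / n
  sigma_g2 <- h_opt * s2
  sigma_e2 <- (1 - h_opt) * s2
  vbar <- mean(lam)
  fit <- structure(list(
    coefficients = stats::setNames(drop(b), colnames(X)),
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    h2 = sigma_g2 * vbar / (sigma_g2 * vbar + sigma_e2),
    loglik = -0.5 * neg2ll(h_opt),
    r = drop(y - X %*% b),
    eigen = list(vectors = U, values = lam, ids = keig$ids),
    omega_diag = sigma_g2 * lam + sigma_e2,
    reml = reml, n = n),
    class = "polygenic_fit")
  fit
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat(sprintf("Polygenic %s fit: n = %d\n", if (x$reml) "REML" else "ML", x$n))
  cat(sprintf("  sigma_g2 = %.4f  sigma_e2 = %.4f  h2 = %.3f  logLik = %.2f\n",
              x$sigma_g2, x$sigma_e2, x$h2, x$loglik))
  invisible(x)
}

# Apply Omega^{-1/2} (whitening) to a vector/matrix using the stored eigen
# representation of the fit.
omega_whiten <- function(fit, x) {
  Ux <- crossprod(fit$eigen$vectors, x)
  Ux / sqrt(fit$omega_diag)
}
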