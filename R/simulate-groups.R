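#' Simulate two labelled groups of multivariate glycome traits
#'
#' Emulates the design of a small knockout-versus-wild-type glycome
#' comparison: two groups of multivariate-normal trait vectors differing by
#' a mean-shift vector, with a common (positive semidefinite) covariance.
#'
#' @param n_per_group length-2 integer (group A, group B sizes).
#' @param n_traits number of traits (default 77).
#' @param mean_shift scalar or length-`n_traits` shift added to group A.
#' @param covariance covariance matrix (default identity).
#' @param seed optional integer seed.
#' @return list with matrices `a` and `b` (samples x traits).
#' @export
simulate_group_glycomes <- function(n_per_group = c(5, 5), n_traits = 77,
                                    mean_shift = 0, covariance = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(covariance)) covariance <- diag(n_traits)
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == n_traits, ncol(covariance) == n_traits)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("covariance is not positive semidefinite")
  shift <- rep_len(mean_shift, n_traits)
  L <- chol(covariance + diag(1e-10, n_traits))
  draw <- function(n, mu) {
    z <- matrix(stats::rnorm(n * n_traits), n, n_traits) %*% L
    sweep(z, 2L, mu, "+")
  }
  a <- draw(n_per_group[1], shift)
  b <- draw(n_per_group[2], rep(0, n_traits))
  colnames(a) <- colnames(b) <- sprintf("IGP%d", seq_len(n_traits))
  rownames(a) <- sprintf("A%02d", seq_len(n_per_group[1]))
  rownames(b) <- sprintf("B%02d", seq_len(n_per_group[2]))
  list(a = a, b = b)
}

#' Simulate a case-control biomarker dataset
#'
#' The biomarker is binormal with equal unit variance in both status
#' groups and standardized mean difference `delta` (cases shifted), so its
#' theoretical AUC is `pnorm(delta / sqrt(2))`. Age, sex and an admixture
#' fraction are drawn independently of status, emulating a matched design
#' in which the covariates carry no predictive signal.
#'
#' @param n_cases,n_controls group sizes.
#' @param delta standardized case-control mean difference (>= 0).
#' @param seed optional integer seed.
#' @return data frame `status` (1 = case), `biomarker`, `age`, `sex`
#'   (1/2), `admixture`.
#' @export
simulate_case_control <- function(n_cases = 101, n_controls = 183, delta = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (delta < 0) stop("delta must be non-negative")
  n <- n_cases + n_controls
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  data.frame(
    status = status,
    biomarker = stats::rnorm(n) + delta * status,
    age = stats::runif(n, 18, 93),
    sex = stats::rbinom(n, 1L, 0.5) + 1L,
    admixture = stats::rbeta(n, 8, 2))
}
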