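#' Per-trait two-group comparison table
#'
#' For every trait: group means, their ratio, and a two-sided pooled
#' variance (Student) t-test for equality of means, laid out as in a
#' knockout-vs-wild-type or case-vs-control comparison table. Welch's
#' unequal-variance test is available behind a flag.
#'
#' Traits may be residualized on covariates first (see
#' [residualize_traits()]) so that means stay on the original measurement
#' scale while covariate effects are removed.
#'
#' @param group_a,group_b samples x traits matrices with matching columns.
#' @param welch use Welch's t instead of the pooled test.
#' @return data frame `trait`, `mean_a`, `mean_b`, `ratio` (a/b), `t`,
#'   `df`, `p`. Zero pooled variance yields `NA` p, flagged in the
#'   `degenerate` column.
#' @export
trait_ttests <- function(group_a, group_b, welch = FALSE) {
  group_a <- as.matrix(group_a); group_b <- as.matrix(group_b)
  stopifnot(identical(colnames(group_a), colnames(group_b)))
  res <- lapply(seq_len(ncol(group_a)), function(j) {
    a <- group_a[, j]; b <- group_b[, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      stop("each group needs >= 2 non-missing values per trait")
    ma <- mean(a); mb <- mean(b)
    if (welch) {
      vv <- stats::var(a) / length(a) + stats::var(b) / length(b)
      df <- vv^2 / ((stats::var(a) / length(a))^2 / (length(a) - 1) +
                    (stats::var(b) / length(b))^2 / (length(b) - 1))
      tt <- (ma - mb) / sqrt(vv)
    } else {
      df <- length(a) + length(b) - 2
      sp2 <- ((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) / df
      tt <- if (sp2 > 0)
        (ma - mb) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      else NA_real_
    }
    data.frame(trait = colnames(group_a)[j], mean_a = ma, mean_b = mb,
               ratio = if (mb != 0) ma / mb else NA_real_,
               t = tt, df = df,
               p = if (is.na(tt)) NA_real_ else
                 2 * stats::pt(-abs(tt), df = df),
               degenerate = is.na(tt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Residualize traits on covariates, keeping the measurement scale
#'
#' Removes least-squares covariate effects from each trait but adds the
#' grand mean back, so group means remain interpretable (unlike the
#' rank-normalized z-scores used for association testing).
#'
#' @param traits samples x traits matrix.
#' @param covariates data frame / matrix aligned with the rows.
#' @return matrix of adjusted traits.
#' @export
residualize_traits <- function(traits, covariates) {
  traits <- as.matrix(traits)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  out <- traits
  for (j in seq_len(ncol(traits))) {
    ok <- !is.na(traits[, j]) & stats::complete.cases(X)
    f <- stats::lm.fit(X[ok, , drop = FALSE], traits[ok, j])
    out[ok, j] <- f$residuals + mean(traits[ok, j])
    out[!ok, j] <- NA_real_
  }
  out
}

#' Hotelling's T-squared statistic for two multivariate samples
#'
#' `T2 = n1 n2 / (n1 + n2) * d' S^+ d` with `d` the difference of group
#' mean vectors and `S^+` the Moore-Penrose pseudo-inverse of the pooled
#' within-group covariance. With more traits than within-group degrees of
#' freedom (e.g. 77 traits on 5 + 5 animals) `S` is singular; the
#' pseudo-inverse restricts the statistic to the span actually observed,
#' which is a valid fixed statistic for the permutation reference
#' distribution used by [hotelling_permutation()]. In the univariate case
#' T2 equals the squared pooled t statistic.
#'
#' @param group_a,group_b samples x traits matrices (>= 2 rows each).
#' @param tol relative pseudo-inverse tolerance (default 1e-10).
#' @return numeric T2 with attribute `rank_deficient`.
#' @export
hotelling_t2 <- function(group_a, group_b, tol = 1e-10) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  d <- colMeans(A) - colMeans(B)
  S <- ((n1 - 1) * stats::cov(A) + (n2 - 1) * stats::cov(B)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% MASS::ginv(S, tol = tol) %*% d)
  attr(t2, "rank_deficient") <- ncol(A) > (n1 + n2 - 2)
  t2
}

#' Permutation test of the global glycome difference
#'
#' Empirical null distribution of Hotelling's T2 obtained by permuting the
#' group labels without replacement, preserving group sizes; the empirical
#' p-value is the proportion of permuted statistics greater than or equal
#' to the observed one. When the number of distinct labelings does not
#' exceed `n_perm`, all of them are enumerated instead of sampling, and
#' the p-value is exact.
#'
#' @inheritParams hotelling_t2
#' @param n_perm number of random permutations (default 10000).
#' @param seed optional integer seed for the permutation stream.
#' @param plus_one use the (b + 1) / (m + 1) estimator instead of the
#'   plain proportion.
#' @return object of class `hotelling_result`: `t2`, `p`, `n_perm`,
#'   `exhaustive`, `rank_deficient`, `perm_t2`.
#' @export
hotelling_permutation <- function(group_a, group_b, n_perm = 10000,
                                  seed = NULL, plus_one = FALSE, tol = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  n1 <- nrow(A); n2 <- nrow(B)
  pool <- rbind(A, B)
  obs <- hotelling_t2(A, B, tol = tol)
  n <- n1 + n2
  n_distinct <- choose(n, n1)
  exhaustive <- n_distinct <= n_perm
  stat_for <- function(idx_a)
    hotelling_t2(pool[idx_a, , drop = FALSE], pool[-idx_a, , drop = FALSE],
                 tol = tol)
  if (exhaustive) {
    combs <- utils::combn(n, n1)
    perm_t2 <- apply(combs, 2L, stat_for)
  } else {
    perm_t2 <- vapply(seq_len(n_perm), function(i) stat_for(sample.int(n, n1)),
                      numeric(1))
  }
  m <- length(perm_t2)
  hits <- sum(perm_t2 >= as.numeric(obs) - 1e-12)
  p <- if (plus_one) (hits + 1) / (m + 1) else hits / m
  structure(list(t2 = as.numeric(obs), p = p, n_perm = m,
                 exhaustive = exhaustive,
                 rank_deficient = attr(obs, "rank_deficient"),
                 perm_t2 = perm_t2),
            class = "hotelling_result")
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("Hotelling T2 = %.3f, empirical p = %.4g (%s%d permutations%s)\n",
              x$t2, x$p, if (x$exhaustive) "exhaustive, " else "", x$n_perm,
              if (x$rank_deficient) "; pooled covariance rank-deficient" else ""))
  invisible(x)
}

#' Count nominally significant traits in a comparison table
#'
#' @param comparison a [trait_ttests()] table.
#' @param alpha nominal level (default 0.05); counting is strict
#'   (`p < alpha`).
#' @return list `count`, `fraction`, `n_traits`.
#' @export
count_nominal <- function(comparison, alpha = 0.05) {
  p <- comparison$p
  count <- sum(p < alpha, na.rm = TRUE)
  list(count = count, fraction = count / length(p), n_traits = length(p))
}
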