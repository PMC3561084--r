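test_that("per-trait t-tests match the pooled-variance oracle and stats::t.test", {
  a <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(c(4, 5, 6), ncol = 1, dimnames = list(NULL, "x"))
  tab <- trait_ttests(a, b)
  expect_equal(tab$t, pooled_t_oracle(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  expect_equal(tab$t, -3.674, tolerance = 1e-3)
  ref <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tab$p, ref$p.value, tolerance = 1e-12)
  expect_equal(tab$df, 4)
  # Welch variant matches stats::t.test default
  set.seed(61)
  aa <- matrix(rnorm(8, sd = 3), ncol = 1, dimnames = list(NULL, "x"))
  bb <- matrix(rnorm(12), ncol = 1, dimnames = list(NULL, "x"))
  tw <- trait_ttests(aa, bb, welch = TRUE)
  refw <- t.test(aa, bb)
  expect_equal(tw$p, refw$p.value, tolerance = 1e-10)
})

test_that("the comparison table reproduces printed mean-ratio layout", {
  g <- groups_with_means(c(IGP8 = 8.91), c(IGP8 = 7.44))
  tab <- trait_ttests(g$a, g$b)
  expect_equal(tab$mean_a, 8.91, tolerance = 1e-10)
  expect_equal(tab$mean_b, 7.44, tolerance = 1e-10)
  expect_equal(round(tab$ratio, 2), 1.20)
})

test_that("identical groups and degenerate variance are handled", {
  m <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("u", "v")))
  tab <- trait_ttests(m, m)
  expect_equal(tab$t, c(0, 0))
  expect_equal(tab$p, c(1, 1))
  cst <- matrix(1, 4, 1, dimnames = list(NULL, "w"))
  tab2 <- trait_ttests(cst, cst)
  expect_true(is.na(tab2$p))
  expect_true(tab2$degenerate)
})

test_that("Hotelling T2 reduces to the squared pooled t in one dimension", {
  set.seed(62)
  a <- matrix(rnorm(7), ncol = 1, dimnames = list(NULL, "x"))
  b <- matrix(rnorm(9) + 1, ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(as.numeric(hotelling_t2(a, b)),
               pooled_t_oracle(drop(a), drop(b))^2, tolerance = 1e-12)
  expect_equal(as.numeric(hotelling_t2(a, a)), 0)
  expect_error(hotelling_t2(a[1, , drop = FALSE], b), "at least 2")
})

test_that("rank-deficient T2 equals the statistic on the observed span", {
  set.seed(63)
  g <- simulate_group_glycomes(c(5, 5), 77, mean_shift = 0.5)
  t2_full <- hotelling_t2(g$a, g$b)
  expect_true(attr(t2_full, "rank_deficient"))
  # oracle: project onto the principal subspace spanned by the pooled
  # within-group variation plus the mean difference, then use a dense solve
  centered <- rbind(sweep(g$a, 2, colMeans(g$a)), sweep(g$b, 2, colMeans(g$b)))
  basis <- svd(rbind(centered, colMeans(g$a) - colMeans(g$b)))$v[, 1:9]
  t2_proj <- hotelling_t2(g$a %*% basis, g$b %*% basis)
  expect_equal(as.numeric(t2_full), as.numeric(t2_proj), tolerance = 1e-6)
})

test_that("T2 is invariant under common invertible affine transforms when S is full rank", {
  set.seed(64)
  a <- matrix(rnorm(40), 10, 4)
  b <- matrix(rnorm(40) + 0.5, 10, 4)
  t2 <- hotelling_t2(a, b)
  M <- matrix(rnorm(16), 4, 4)
  while (abs(det(M)) < 0.1) M <- matrix(rnorm(16), 4, 4)
  shift <- rnorm(4)
  tr <- function(x) sweep(x %*% M, 2, shift, "+")
  expect_equal(as.numeric(hotelling_t2(tr(a), tr(b))), as.numeric(t2),
               tolerance = 1e-6)
})

test_that("tiny designs enumerate all labelings and match brute force", {
  set.seed(65)
  a <- matrix(rnorm(4), 2, 2)
  b <- matrix(rnorm(4) + 2, 2, 2)
  res <- hotelling_permutation(a, b, n_perm = 10000)
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(4, 2))
  pool <- rbind(a, b)
  stats <- apply(utils::combn(4, 2), 2, function(idx)
    as.numeric(hotelling_t2(pool[idx, , drop = FALSE],
                            pool[-idx, , drop = FALSE])))
  expect_equal(sort(res$perm_t2), sort(stats), tolerance = 1e-12)
  expect_equal(res$p, mean(stats >= res$t2 - 1e-12))
  expect_gte(res$p, 1 / choose(4, 2))
})

test_that("permutation p is label-symmetric and seed-reproducible", {
  set.seed(66)
  a <- matrix(rnorm(12), 3, 4)
  b <- matrix(rnorm(12) + 0.8, 3, 4)
  r1 <- hotelling_permutation(a, b, n_perm = 500, seed = 9)   # exhaustive
  r2 <- hotelling_permutation(b, a, n_perm = 500, seed = 9)
  expect_true(r1$exhaustive)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$t2, r2$t2)
  r3 <- hotelling_permutation(a, b, n_perm = 500, seed = 9)
  expect_identical(r1$perm_t2, r3$perm_t2)
  # plus-one estimator never returns zero
  r4 <- hotelling_permutation(a, b, n_perm = 200, seed = 10, plus_one = TRUE)
  expect_gt(r4$p, 0)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(67)
  ps <- vapply(1:150, function(i) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    hotelling_permutation(a, b, n_perm = 200)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("nominal counting is strict and monotone in alpha", {
  tab <- data.frame(p = c(0.01, 0.04, 0.5, 0.9))
  res <- count_nominal(tab)
  expect_equal(res$count, 2L)
  expect_equal(res$fraction, 0.5)
  expect_equal(count_nominal(data.frame(p = rep(1, 5)))$count, 0L)
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  counts <- vapply(alphas, function(a) count_nominal(tab, a)$count, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("residualizing traits removes covariate effects but keeps the mean scale", {
  set.seed(68)
  n <- 120
  age <- runif(n, 20, 80)
  traits <- cbind(t1 = 5 + 0.1 * age + rnorm(n), t2 = 30 + rnorm(n))
  adj <- residualize_traits(traits, data.frame(age = age))
  expect_lt(abs(cor(adj[, "t1"], age)), 1e-10)
  expect_equal(mean(adj[, "t1"]), mean(traits[, "t1"]), tolerance = 1e-10)
  expect_equal(mean(adj[, "t2"]), mean(traits[, "t2"]), tolerance = 1e-10)
})
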