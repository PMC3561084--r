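#' Logistic regression fit with separation diagnostics
#'
#' Thin wrapper over maximum-likelihood logistic regression (IRLS via
#' `stats::glm`) that records whether the fit converged and whether
#' complete separation was detected (diverging coefficients / fitted
#' probabilities at the 0-1 boundary).
#'
#' @param status binary outcome (0/1 or logical).
#' @param predictors data frame / matrix of predictors.
#' @return object of class `logistic_fit`: `coefficients`, `se`,
#'   `fitted`, `converged`, `separation`, `n`, and the underlying `glm`.
#' @export
fit_logistic <- function(status, predictors) {
  status <- as.integer(status)
  stopifnot(all(status %in% 0:1))
  df <- data.frame(.status = status, as.data.frame(predictors))
  boundary_warn <- FALSE
  g <- withCallingHandlers(
    stats::glm(.status ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        boundary_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(g)
  separation <- boundary_warn || any(abs(stats::coef(g)) > 15, na.rm = TRUE)
  structure(list(coefficients = stats::coef(g),
                 se = sm$coefficients[, "Std. Error"],
                 fitted = stats::fitted(g),
                 converged = g$converged && !separation,
                 separation = separation,
                 n = nrow(df), glm = g),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d)%s\n", x$n,
              if (x$separation) " -- separation detected" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the Mann-Whitney formulation (ties count 0.5), which equals the
#' trapezoidal area under the empirical ROC curve; the 95% CI uses the
#' DeLong placement-value variance estimator.
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param status binary labels (1 = case).
#' @return object of class `roc_result`: `auc`, `ci` (length 2),
#'   `n_cases`, `n_controls`, `method`.
#' @export
roc_auc <- function(scores, status) {
  status <- as.integer(status)
  ok <- !is.na(scores) & !is.na(status)
  scores <- scores[ok]; status <- status[ok]
  cases <- scores[status == 1]; controls <- scores[status == 0]
  n1 <- length(cases); n0 <- length(controls)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(c(cases, controls), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  v10 <- vapply(cases, function(s)
    (sum(controls < s) + 0.5 * sum(controls == s)) / n0, numeric(1))
  v01 <- vapply(controls, function(s)
    (sum(cases > s) + 0.5 * sum(cases == s)) / n1, numeric(1))
  v <- if (n1 > 1) stats::var(v10) / n1 else 0
  v <- v + if (n0 > 1) stats::var(v01) / n0 else 0
  half <- stats::qnorm(0.975) * sqrt(v)
  structure(list(auc = auc,
                 ci = c(max(0, auc - half), min(1, auc + half)),
                 n_cases = n1, n_controls = n0, method = "full-data (DeLong CI)"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls [%s]\n",
              x$auc, x$ci[1], x$ci[2], x$n_cases, x$n_controls, x$method))
  invisible(x)
}

#' Repeated stratified split-sample cross-validation of a biomarker model
#'
#' Splits the data into a training set (`train_frac`, stratified by status
#' so the case:control ratio is preserved; sizes are floored) and a test
#' set, fits the logistic model on the training set, scores the test set,
#' and records the test AUC; repeated `n_rep` times. Returns the mean AUC
#' with a percentile 95% CI over repeats.
#'
#' @param data data frame containing `status_col` and the predictors.
#' @param predictors character vector of predictor column names.
#' @param status_col outcome column name (default "status").
#' @param train_frac training fraction (default 2/3).
#' @param n_rep number of repeats (default 1000).
#' @param seed optional integer seed.
#' @return object of class `roc_result` with `auc` (mean over repeats),
#'   percentile `ci`, `per_repeat` AUC vector and `n_skipped`.
#' @export
repeated_split_cv <- function(data, predictors, status_col = "status",
                              train_frac = 2/3, n_rep = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- data[stats::complete.cases(data[c(status_col, predictors)]), ]
  status <- as.integer(data[[status_col]])
  idx_case <- which(status == 1); idx_ctrl <- which(status == 0)
  n1 <- floor(length(idx_case) * train_frac)
  n0 <- floor(length(idx_ctrl) * train_frac)
  if (n1 < 2L || n0 < 2L || n1 >= length(idx_case) || n0 >= length(idx_ctrl))
    stop("too few cases/controls for a stratified split")
  fml <- stats::as.formula(paste(status_col, "~",
                                 paste(predictors, collapse = " + ")))
  aucs <- rep(NA_real_, n_rep)
  for (i in seq_len(n_rep)) {
    train <- c(sample(idx_case, n1), sample(idx_ctrl, n0))
    fit <- tryCatch(
      suppressWarnings(stats::glm(fml, data = data[train, ],
                                  family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit)) next
    test <- setdiff(seq_len(nrow(data)), train)
    sc <- stats::predict(fit, newdata = data[test, ], type = "link")
    aucs[i] <- roc_auc(sc, status[test])$auc
  }
  skipped <- sum(is.na(aucs))
  if (skipped > 0.05 * n_rep)
    stop(skipped, " of ", n_rep, " cross-validation repeats failed")
  aucs_ok <- aucs[!is.na(aucs)]
  structure(list(auc = mean(aucs_ok),
                 ci = unname(stats::quantile(aucs_ok, c(0.025, 0.975))),
                 n_cases = length(idx_case), n_controls = length(idx_ctrl),
                 method = sprintf("%d-fold repeated %d/%d split CV (percentile CI)",
                                  n_rep, round(100 * train_frac),
                                  round(100 * (1 - train_frac))),
                 per_repeat = aucs, n_skipped = skipped),
            class = "roc_result")
}

#' Evaluate a biomarker panel against a baseline covariate model
#'
#' Fits two nested logistic models on the same listwise-complete rows --
#' baseline covariates only, and baseline plus biomarker(s) -- and reports
#' full-data AUC (DeLong CI) for both, optionally with repeated
#' split-sample cross-validation.
#'
#' @param data data frame with `status_col`, covariates and biomarkers.
#' @param baseline character vector of baseline covariate columns.
#' @param biomarkers character vector of biomarker columns.
#' @param status_col outcome column (default "status").
#' @param cv run [repeated_split_cv()] for both models.
#' @param n_rep,seed passed to the cross-validation.
#' @return list with `baseline` and `augmented` (each: `fit`, `roc`, and
#'   `cv` when requested) plus `n_used`.
#' @export
evaluate_panel <- function(data, baseline, biomarkers, status_col = "status",
                           cv = FALSE, n_rep = 1000, seed = NULL) {
  cols <- c(status_col, baseline, biomarkers)
  stopifnot(all(cols %in% names(data)))
  dup <- duplicated(as.list(data[c(baseline, biomarkers)]))
  if (any(dup)) {
    warning("dropping duplicated predictor column(s): ",
            paste(c(baseline, biomarkers)[dup], collapse = ", "))
    keep <- c(baseline, biomarkers)[!dup]
    baseline <- intersect(baseline, keep)
    biomarkers <- intersect(biomarkers, keep)
  }
  for (bm in biomarkers)
    if (stats::var(data[[bm]], na.rm = TRUE) == 0)
      stop("biomarker '", bm, "' is constant")
  use <- stats::complete.cases(data[cols])
  d <- data[use, ]
  one <- function(preds) {
    fit <- fit_logistic(d[[status_col]], d[preds])
    roc <- roc_auc(fit$fitted, d[[status_col]])
    out <- list(fit = fit, roc = roc)
    if (cv) out$cv <- repeated_split_cv(d, preds, status_col = status_col,
                                        n_rep = n_rep, seed = seed)
    out
  }
  list(baseline = one(baseline),
       augmented = one(c(baseline, biomarkers)),
       n_used = nrow(d))
}
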