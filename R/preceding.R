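#' Construct a study sample
#'
#' Bundles a predictor matrix and a binary outcome drawn from a population,
#' and records which columns are non-degenerate (take more than one distinct
#' value in this sample). Sparse binary predictors routinely collapse to a
#' constant in small subsamples; such columns carry no information for either
#' regression or tree splitting and are tracked explicitly.
#'
#' @param X numeric matrix with named columns.
#' @param y 0/1 outcome vector, `length(y) == nrow(X)`.
#' @return an object of class `study_sample` with elements `X`, `y`,
#'   `nondegenerate` (character vector of column names).
#' @export
study_sample <- function(X, y) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(y))
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  nd <- colnames(X)[nondegenerate_mask(X)]
  structure(
    list(X = X, y = as.integer(y), nondegenerate = nd),
    class = "study_sample"
  )
}

# a column is non-degenerate iff it has >= 2 distinct observed values
nondegenerate_mask <- function(X) {
  apply(X, 2, max) > apply(X, 2, min)
}

#' @export
print.study_sample <- function(x, ...) {
  cat(sprintf(
    "study sample: n = %d, p = %d (%d non-degenerate), event rate %.3f\n",
    nrow(x$X), ncol(x$X), length(x$nondegenerate), mean(x$y)
  ))
  invisible(x)
}

#' Drop degenerate columns from a study sample
#'
#' Restricts the sample to columns with at least two distinct observed
#' values. The number of columns removed is recorded in the `"n_dropped"`
#' attribute.
#'
#' @param sample a [study_sample()].
#' @return a `study_sample` containing only non-degenerate columns.
#' @export
drop_degenerate <- function(sample) {
  stopifnot(inherits(sample, "study_sample"))
  keep <- sample$nondegenerate
  if (length(keep) == 0) stop("all columns are degenerate: nothing to train on")
  out <- study_sample(sample$X[, keep, drop = FALSE], sample$y)
  attr(out, "n_dropped") <- ncol(sample$X) - length(keep)
  out
}

new_selection_result <- function(method, selected, intercept, coefficients,
                                 n_candidates) {
  stopifnot(length(selected) == length(coefficients),
            identical(names(coefficients), selected) || length(selected) == 0)
  structure(
    list(
      method = method,
      selected = as.character(selected),
      intercept = as.numeric(intercept),
      coefficients = coefficients,
      empty = length(selected) == 0,
      n_candidates = n_candidates
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection result (%s): %d of %d candidates selected%s\n",
              x$method, length(x$selected), x$n_candidates,
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Fit a Lasso logistic preceding study
#'
#' L1-penalized logistic regression over a penalty path, with the penalty
#' chosen by minimizing the 10-fold cross-validated binomial deviance.
#' Variables with a nonzero coefficient at the chosen penalty constitute the
#' selection. Predictors are left unstandardized: binary indicators already
#' share the 0/1 scale, and standardizing would up-weight the rare columns.
#'
#' @param sample a [study_sample()]; degenerate columns should already be
#'   removed (see [drop_degenerate()]).
#' @param n_cv_folds number of cross-validation folds.
#' @param seed integer seed controlling the fold assignment.
#' @return a `selection_result` with `method = "lasso"`.
#' @export
fit_lasso_study <- function(sample, n_cv_folds = 10, seed = 1L) {
  stopifnot(inherits(sample, "study_sample"))
  y <- sample$y
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    stop("need at least 2 observations per outcome class")
  }
  X <- sample$X[, sample$nondegenerate, drop = FALSE]
  pad <- ncol(X) < 2
  if (pad) X <- cbind(X, `..pad..` = 0) # glmnet requires >= 2 columns
  foldid <- with_seed(
    derive_seed(seed, "cvfolds"),
    sample(rep(seq_len(n_cv_folds), length.out = length(y)))
  )
  cv <- glmnet::cv.glmnet(
    X, y, family = "binomial", type.measure = "deviance",
    foldid = foldid, standardize = FALSE
  )
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  intercept <- cf["(Intercept)"]
  cf <- cf[setdiff(names(cf), c("(Intercept)", "..pad.."))]
  sel <- names(cf)[cf != 0]
  new_selection_result("lasso", sel, intercept, cf[sel],
                       n_candidates = length(sample$nondegenerate))
}

# Wald test of the slope in a univariable logistic model with a single
# binary 0/1 predictor. The MLE is the 2x2-table log odds ratio and the
# Wald standard error is sqrt of the summed reciprocal cell counts, so the
# p-value is computed in closed form (identical to glm, orders of magnitude
# faster at p ~ 1000 candidates). Any empty cell drives the SE to infinity
# and the Wald statistic to zero: the variable is never selected.
wald_p_binary <- function(x, y) {
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  n00 <- sum(x == 0 & y == 0)
  if (min(n11, n10, n01, n00) == 0) return(1)
  beta <- log((n11 * n00) / (n10 * n01))
  se <- sqrt(1 / n11 + 1 / n10 + 1 / n01 + 1 / n00)
  2 * stats::pnorm(-abs(beta / se))
}

wald_p_numeric <- function(x, y) {
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  s <- summary(fit)$coefficients
  if (nrow(s) < 2) return(1)
  s[2, 4]
}

#' Fit a univariate-selection preceding study
#'
#' Screens every candidate predictor with a Wald test of the slope in a
#' univariable logistic regression; predictors significant at `alpha` enter
#' one multivariable logistic model whose coefficients populate the result.
#' If the multivariable fit shows separation or fails to converge, a
#' ridge-stabilized fit (L2 penalty `1e-6`) is used instead, with a warning.
#'
#' @param sample a [study_sample()]; degenerate columns should already be
#'   removed.
#' @param alpha significance level for the univariable screen.
#' @return a `selection_result` with `method = "univariate"`.
#' @export
fit_univariate_study <- function(sample, alpha = 0.05) {
  stopifnot(inherits(sample, "study_sample"), alpha >= 0, alpha <= 1)
  y <- sample$y
  if (min(table(factor(y, levels = c(0, 1)))) < 2) {
    stop("need at least 2 observations per outcome class")
  }
  X <- sample$X[, sample$nondegenerate, drop = FALSE]
  is_bin <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  pvals <- vapply(seq_len(ncol(X)), function(j) {
    if (is_bin[j]) wald_p_binary(X[, j], y) else wald_p_numeric(X[, j], y)
  }, numeric(1))
  sel <- colnames(X)[pvals < alpha]

  if (length(sel) == 0) {
    intercept <- logit(clip_prob(mean(y)))
    return(new_selection_result("univariate", character(0), intercept,
                                stats::setNames(numeric(0), character(0)),
                                n_candidates = ncol(X)))
  }

  Xs <- X[, sel, drop = FALSE]
  fit_ok <- TRUE
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, Xs), y,
                   family = stats::binomial()),
    warning = function(cond) {
      w <<- conditionMessage(cond)
      invokeRestart("muffleWarning")
    }
  )
  cf <- fit$coefficients
  if (!fit$converged || anyNA(cf) || max(abs(cf)) > 20 || !is.null(w)) {
    fit_ok <- FALSE
  }
  if (!fit_ok) {
    warning("multivariable fit after univariate selection unstable ",
            "(separation or non-convergence); using ridge-stabilized fit")
    Xr <- if (ncol(Xs) < 2) cbind(Xs, `..pad..` = 0) else Xs
    rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    cf <- as.matrix(stats::coef(rf))[, 1]
    cf <- cf[c("(Intercept)", sel)]
  }
  new_selection_result("univariate", sel, cf[["(Intercept)"]],
                       cf[sel], n_candidates = ncol(X))
}

#' Predict from a fitted preceding-study model
#'
#' Evaluates `expit(intercept + sum coef * x)` on new data. Every selected
#' variable must be present as a column of `X`; columns that are degenerate
#' in `X` are simply evaluated at their constant observed value, so a model
#' carried over from a preceding study can be applied unchanged.
#'
#' @param result a `selection_result`.
#' @param X numeric matrix with named columns covering `result$selected`.
#' @return probability vector in (0, 1).
#' @export
predict_logistic <- function(result, X) {
  stopifnot(inherits(result, "selection_result"), is.matrix(X))
  missing_vars <- setdiff(result$selected, colnames(X))
  if (length(missing_vars) > 0) {
    stop("selected variable(s) absent from the data: ",
         paste(missing_vars, collapse = ", "))
  }
  eta <- rep(result$intercept, nrow(X))
  if (length(result$selected) > 0) {
    eta <- eta + drop(X[, result$selected, drop = FALSE] %*%
                        result$coefficients)
  }
  expit(eta)
}

#' Write a selection result to delimited text for audit
#'
#' @param result a `selection_result`.
#' @param path output path (`.csv` or `.tsv`).
#' @return the path, invisibly.
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  sep <- delim_for(path)
  df <- data.frame(
    method = result$method,
    variable = c("(Intercept)", result$selected),
    coefficient = c(result$intercept, unname(result$coefficients)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
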