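#' Probability-forest hyperparameters
#'
#' Parameters of the probability random forest: an ensemble of unpruned
#' classification trees, each grown on a bootstrap resample with Gini-index
#' splitting, whose per-tree terminal-node majority votes are averaged into a
#' probability estimate. Defaults follow the documented defaults of
#' `ranger::ranger(probability = TRUE)`: 500 trees, `mtry = floor(sqrt(p))`,
#' minimum node size 10 observations. The 10% minimum-node-size variant is
#' available by giving `min_node_size` as a fraction in (0, 1).
#'
#' @param n_trees number of trees.
#' @param mtry_rule one of `"sqrt"` (use `floor(sqrt(p))`), `"fraction"`,
#'   `"fixed"`.
#' @param mtry_value value used by the `"fraction"`/`"fixed"` rules.
#' @param min_node_size minimum terminal node size; an integer count, or a
#'   fraction of n if in (0, 1).
#' @param seed integer seed; forests are deterministic given it.
#' @return an object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, mtry_rule = c("sqrt", "fraction", "fixed"),
                          mtry_value = NULL, min_node_size = 10, seed = 1L) {
  mtry_rule <- match.arg(mtry_rule)
  stopifnot(n_trees >= 1, min_node_size > 0)
  if (mtry_rule != "sqrt" && is.null(mtry_value)) {
    stop("mtry_value is required for rule '", mtry_rule, "'")
  }
  structure(
    list(n_trees = as.integer(n_trees), mtry_rule = mtry_rule,
         mtry_value = mtry_value, min_node_size = min_node_size,
         seed = as.integer(seed)),
    class = "forest_params"
  )
}

resolve_mtry <- function(params, p) {
  m <- switch(params$mtry_rule,
    sqrt = floor(sqrt(p)),
    fraction = floor(params$mtry_value * p),
    fixed = params$mtry_value
  )
  max(1L, min(as.integer(m), p))
}

resolve_min_node_size <- function(params, n) {
  mns <- params$min_node_size
  if (mns < 1) mns <- ceiling(mns * n)
  as.integer(mns)
}

#' Train a probability random forest
#'
#' Thin wrapper around `ranger::ranger(probability = TRUE)` satisfying the
#' probability-forest contract: bootstrap resamples, Gini splitting, no
#' pruning, random `mtry`-sized candidate sets per node, ensemble-averaged
#' terminal-node votes as probability estimates, fully deterministic given
#' `params$seed` (single-threaded).
#'
#' @param X numeric predictor matrix with named columns (non-degenerate
#'   columns only).
#' @param y 0/1 outcome; both classes must be present.
#' @param params a [forest_params()].
#' @return an object of class `probability_forest`.
#' @export
train_probability_forest <- function(X, y, params = forest_params()) {
  stopifnot(is.matrix(X), inherits(params, "forest_params"))
  if (ncol(X) < 1) stop("at least one predictor column is required")
  if (length(unique(y)) < 2) stop("outcome has a single class; cannot train")
  yf <- factor(y, levels = c(0, 1))
  fit <- ranger::ranger(
    x = X, y = yf,
    probability = TRUE,
    num.trees = params$n_trees,
    mtry = resolve_mtry(params, ncol(X)),
    min.node.size = resolve_min_node_size(params, nrow(X)),
    splitrule = "gini",
    replace = TRUE,
    seed = params$seed,
    num.threads = 1,
    verbose = FALSE
  )
  structure(
    list(fit = fit, variables = colnames(X), params = params),
    class = "probability_forest"
  )
}

#' Predict event probabilities from a probability forest
#'
#' @param object a `probability_forest`.
#' @param newdata numeric matrix containing the training columns.
#' @param ... unused.
#' @return vector of event probabilities in \[0, 1\].
#' @export
predict.probability_forest <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  missing_vars <- setdiff(object$variables, colnames(newdata))
  if (length(missing_vars) > 0) {
    stop("columns absent from newdata: ", paste(missing_vars, collapse = ", "))
  }
  pr <- stats::predict(object$fit,
                       data = newdata[, object$variables, drop = FALSE],
                       num.threads = 1)$predictions
  unname(pr[, "1"])
}

#' Pick the better-performing preceding model
#'
#' Applies both preceding-study models unchanged to the current sample and
#' compares their AUROC against the current outcome. Ties go to the Lasso
#' model (the methodologically stronger preceding study).
#'
#' @param sel_lasso,sel_uni nonempty `selection_result`s.
#' @param current a [study_sample()].
#' @return `"lasso"` or `"univariate"`.
#' @export
m5_pick_winner <- function(sel_lasso, sel_uni, current) {
  stopifnot(!sel_lasso$empty, !sel_uni$empty, inherits(current, "study_sample"))
  auc_l <- auroc(predict_logistic(sel_lasso, current$X), current$y)
  auc_u <- auroc(predict_logistic(sel_uni, current$X), current$y)
  if (auc_u > auc_l) "univariate" else "lasso"
}

#' Build the candidate-variable set for one modeling strategy
#'
#' Constructs the variable set fed to the current-study forest for one of the
#' five strategies:
#' \describe{
#'   \item{M1}{all non-degenerate current-study variables (naive forest).}
#'   \item{M2}{the Lasso preceding study's selection.}
#'   \item{M3}{the intersection of the two preceding selections.}
#'   \item{M4}{the union of the two preceding selections.}
#'   \item{M5}{the selection of whichever preceding model has the higher
#'     AUROC when applied unchanged to the current sample.}
#' }
#' An empty selection is treated as absent background knowledge, resolved by
#' the fallback ladder: M2 falls back to all variables; M3 to M4's result;
#' M4 to all variables; M5 to the other model, or to all variables when both
#' selections are empty. Variables degenerate in the current sample are
#' removed before resolution, so a set emptied by degeneracy falls back the
#' same way.
#'
#' @param method one of `"M1"`, `"M2"`, `"M3"`, `"M4"`, `"M5"`.
#' @param sel_lasso,sel_uni `selection_result`s from the preceding studies.
#' @param current a [study_sample()] for the current study.
#' @return an object of class `strategy_set`: list with `method`,
#'   `variables`, `fallback` (one of `"none"`, `"all-variables"`,
#'   `"union-substitute"`, `"other-model"`, `"both-empty-all"`) and
#'   `m5_winner` (`"lasso"`, `"univariate"` or `NA`).
#' @export
build_strategy_set <- function(method, sel_lasso, sel_uni, current) {
  if (!method %in% c("M1", "M2", "M3", "M4", "M5")) {
    stop("unknown method label: ", method)
  }
  stopifnot(inherits(current, "study_sample"))
  nd <- current$nondegenerate
  # degenerate-in-current variables are unusable by the forest: filter the
  # selections first, so emptiness by degeneracy triggers the same ladder
  L <- intersect(sel_lasso$selected, nd)
  U <- intersect(sel_uni$selected, nd)
  winner <- NA_character_
  fallback <- "none"

  vars <- switch(method,
    M1 = nd,
    M2 = if (length(L) > 0) L else {
      fallback <- "all-variables"
      nd
    },
    M3 = {
      inter <- intersect(L, U)
      if (length(inter) > 0) inter
      else {
        un <- union(L, U)
        if (length(un) > 0) {
          fallback <- "union-substitute"
          un
        } else {
          fallback <- "all-variables"
          nd
        }
      }
    },
    M4 = {
      un <- union(L, U)
      if (length(un) > 0) un else {
        fallback <- "all-variables"
        nd
      }
    },
    M5 = {
      if (length(L) > 0 && length(U) > 0) {
        winner <- m5_pick_winner(sel_lasso, sel_uni, current)
        if (winner == "lasso") L else U
      } else if (length(L) > 0) {
        fallback <- "other-model"
        winner <- "lasso"
        L
      } else if (length(U) > 0) {
        fallback <- "other-model"
        winner <- "univariate"
        U
      } else {
        fallback <- "both-empty-all"
        nd
      }
    }
  )
  structure(
    list(method = method, variables = vars, fallback = fallback,
         m5_winner = winner),
    class = "strategy_set"
  )
}

#' @export
print.strategy_set <- function(x, ...) {
  cat(sprintf("strategy %s: %d variables (fallback: %s%s)\n",
              x$method, length(x$variables), x$fallback,
              if (!is.na(x$m5_winner)) paste0(", winner: ", x$m5_winner) else ""))
  invisible(x)
}

#' Fit the current-study Lasso comparator
#'
#' The comparator column of the results tables: the same cross-validated
#' Lasso logistic fit as the preceding studies use, trained on the current
#' sample. Shares its implementation with [fit_lasso_study()].
#'
#' @param current a [study_sample()] (degenerate columns removed).
#' @param seed integer seed for the cross-validation folds.
#' @return a `selection_result`; predict with [predict_logistic()].
#' @export
fit_lasso_comparator <- function(current, seed = 1L) {
  fit_lasso_study(current, n_cv_folds = 10, seed = seed)
}

#' Write a strategy set to delimited text for audit
#'
#' @param set a `strategy_set`.
#' @param path output path (`.csv` or `.tsv`).
#' @return the path, invisibly.
#' @export
write_strategy_set <- function(set, path) {
  stopifnot(inherits(set, "strategy_set"))
  sep <- delim_for(path)
  df <- data.frame(
    method = set$method, variable = set$variables,
    fallback = set$fallback, m5_winner = set$m5_winner,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
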