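#' Area under the ROC curve (concordance statistic)
#'
#' Probability, over all (event, non-event) pairs, that the event receives
#' the larger prediction, with tied predictions counting one half. Computed
#' via the rank-sum (Wilcoxon) identity, which is exactly the pairwise
#' definition with the tie convention. Ties are ubiquitous with forest
#' probabilities on sparse binary data, so the convention matters.
#'
#' @param p prediction vector.
#' @param y 0/1 outcome vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(p, y) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predictions and outcomes; ideal value 0.
#'
#' @inheritParams auroc
#' @return nonnegative real.
#' @export
brier <- function(p, y) {
  stopifnot(length(p) == length(y))
  mean((y - p)^2)
}

#' Cross-entropy (summed negative Bernoulli log-likelihood)
#'
#' `-sum(y * log(p) + (1 - y) * log(1 - p))` over the validation
#' observations, after clipping predictions into `[clip, 1 - clip]`. The sum
#' (not the mean) is reported, so magnitudes scale with the validation size.
#' Also returns the largest single-observation contribution, which flags
#' individual predictions that were confidently wrong.
#'
#' @inheritParams auroc
#' @param clip clipping constant for the logarithms.
#' @return list with elements `total` and `max_contribution`.
#' @export
cross_entropy <- function(p, y, clip = 1e-6) {
  stopifnot(length(p) == length(y))
  pc <- clip_prob(p, clip)
  contrib <- -(y * log(pc) + (1 - y) * log(1 - pc))
  list(total = sum(contrib), max_contribution = max(contrib))
}

#' Calibration slope
#'
#' Slope of a univariable logistic regression (with intercept) of the
#' observed outcomes on the log odds of the predictions; ideal value 1.
#' Slopes above 1 indicate underfit (predictions too narrowly scattered
#' around the event rate), below 1 overfit. Degenerate inputs — constant
#' predictions, or a fit that does not converge — yield `NA_real_` with a
#' warning; aggregation excludes and counts them.
#'
#' @inheritParams auroc
#' @param clip clipping constant applied before the logit.
#' @return the slope, or `NA_real_` when it is not estimable.
#' @export
calibration_slope <- function(p, y, clip = 1e-6) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  eta <- logit(clip_prob(p, clip))
  if (stats::sd(eta) == 0) {
    warning("predictions are constant; calibration slope is not estimable")
    return(NA_real_)
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, eta), y, family = stats::binomial())
  )
  if (!fit$converged || anyNA(fit$coefficients)) {
    warning("calibration-slope regression did not converge")
    return(NA_real_)
  }
  unname(fit$coefficients[2])
}

#' Mean squared log calibration slope
#'
#' `mean(log(slope)^2)` across replications: the squared deviation of the
#' log calibration slope from its ideal value of zero, combining average
#' miscalibration with its variability. Non-finite or non-positive slopes
#' are excluded; their count is attached as attribute `"n_excluded"`.
#'
#' @param slopes vector of calibration slopes.
#' @return nonnegative real with attribute `n_excluded`.
#' @export
mse_log_slope <- function(slopes) {
  if (length(slopes) == 0) stop("no slopes supplied")
  ok <- is.finite(slopes) & slopes > 0
  if (!any(ok)) stop("no usable (finite, positive) slopes")
  out <- mean(log(slopes[ok])^2)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Decile-grouped calibration table and plot
#'
#' Groups observations by the deciles (or `n_groups`-tiles) of the predicted
#' probabilities and, per group, computes the mean prediction and the
#' observed outcome rate; overlays the logistic recalibration line (the
#' regression of the outcome on the prediction log odds). Tied predictions
#' that collapse decile boundaries merge the affected groups, with a
#' warning.
#'
#' @inheritParams auroc
#' @param n_groups number of probability groups.
#' @return list with `table` (data frame: `group`, `n`, `mean_pred`,
#'   `obs_rate`), `intercept` and `slope` of the recalibration line, and
#'   `plot` (a ggplot object).
#' @export
calibration_plot <- function(p, y, n_groups = 10) {
  stopifnot(length(p) == length(y), length(p) >= n_groups)
  breaks <- stats::quantile(p, probs = seq(0, 1, length.out = n_groups + 1),
                            type = 7, names = FALSE)
  ub <- unique(breaks)
  if (length(ub) < length(breaks)) {
    warning("tied predictions collapsed ",
            length(breaks) - length(ub), " group boundary(ies); merging")
  }
  if (length(ub) < 2) {
    grp <- factor(rep(1, length(p)))
  } else {
    grp <- cut(p, breaks = ub, include.lowest = TRUE, labels = FALSE)
    grp <- factor(grp)
  }
  tab <- data.frame(
    group = seq_along(levels(grp)),
    n = as.integer(table(grp)),
    mean_pred = as.numeric(tapply(p, grp, mean)),
    obs_rate = as.numeric(tapply(y, grp, mean))
  )
  slope <- calibration_slope(p, y)
  intercept <- NA_real_
  if (is.finite(slope)) {
    eta <- logit(clip_prob(p))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, eta), y, family = stats::binomial())
    )
    intercept <- unname(fit$coefficients[1])
  }
  grid <- seq(min(p), max(p), length.out = 200)
  line_df <- if (is.finite(slope)) {
    data.frame(
      pred = grid,
      recal = expit(intercept + slope * logit(clip_prob(grid)))
    )
  } else {
    data.frame(pred = numeric(0), recal = numeric(0))
  }
  plt <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_pred,
                                           y = .data$obs_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(data = line_df,
                       ggplot2::aes(x = .data$pred, y = .data$recal),
                       colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed outcome rate",
                  title = "Calibration by prediction decile") +
    ggplot2::theme_minimal()
  list(table = tab, intercept = intercept, slope = slope, plot = plt)
}

#' All validation measures for one prediction vector
#'
#' Convenience wrapper computing AUROC, Brier score, calibration slope and
#' cross-entropy (with its maximum contribution) in one call.
#'
#' @inheritParams auroc
#' @param clip shared clipping constant.
#' @return one-row data frame with columns `auroc`, `brier`, `cal_slope`,
#'   `cross_entropy`, `max_ce_contribution`.
#' @export
evaluate_predictions <- function(p, y, clip = 1e-6) {
  ce <- cross_entropy(p, y, clip)
  slope <- suppressWarnings(calibration_slope(p, y, clip))
  data.frame(
    auroc = auroc(p, y),
    brier = brier(p, y),
    cal_slope = slope,
    cross_entropy = ce$total,
    max_ce_contribution = ce$max_contribution
  )
}
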