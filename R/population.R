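#' Configuration for the synthetic plasmode population generator
#'
#' Parameterizes a synthetic stand-in for a prescription-registry style data
#' set: a large table of mostly sparse binary predictors (plus a small number
#' of standardized numeric predictors such as age analogues), and one weakly
#' predictable binary outcome generated from a sparse additive logistic model.
#'
#' The marginal prevalences of the binary predictors are drawn from a
#' piecewise log-linear quantile law anchored at three target quartiles
#' (defaults 1/3371, 1/1530, 1/112 — heavily left-skewed, as is typical of
#' diagnosis/prescription indicator data), with log-uniform tails running from
#' `min_prevalence` up to `max_prevalence`. Columns whose prevalence is below
#' 1/`n_pop` may come out constant: degenerate columns are a designed feature
#' of this kind of data, not an error.
#'
#' Nonzero outcome effects are placed on the `signal_fraction` most prevalent
#' binary columns (common exposures carry the signal; very sparse columns are
#' uninformative at realistic sample sizes) with magnitude `effect_scale` and
#' random signs, and on every numeric column with magnitude
#' `effect_numeric`. The intercept is solved numerically so the population
#' event rate matches `target_event_rate`.
#'
#' @param n_pop number of individuals in the population.
#' @param p_binary number of binary predictor columns.
#' @param p_numeric number of standardized numeric predictor columns.
#' @param prevalence_quartiles length-3 increasing vector: the first quartile,
#'   median and third quartile targeted for the binary prevalences.
#' @param min_prevalence,max_prevalence support of the prevalence law.
#' @param target_event_rate desired population frequency of `y_weak == 1`.
#' @param signal_fraction fraction of binary columns given a nonzero effect.
#' @param effect_scale absolute log-odds effect of each signal binary column.
#' @param effect_numeric log-odds effect per standard deviation of each
#'   numeric column.
#' @param seed integer seed; the whole population is deterministic given it.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_pop = 10000,
                              p_binary = 400,
                              p_numeric = 2,
                              prevalence_quartiles = c(1 / 3371, 1 / 1530, 1 / 112),
                              min_prevalence = 1 / n_pop,
                              max_prevalence = 0.5,
                              target_event_rate = 0.558,
                              signal_fraction = 0.05,
                              effect_scale = 0.34,
                              effect_numeric = 0.21,
                              seed = 1L) {
  stopifnot(
    n_pop >= 4, p_binary >= 1, p_numeric >= 0,
    length(prevalence_quartiles) == 3,
    all(diff(prevalence_quartiles) > 0),
    min_prevalence > 0, max_prevalence < 1,
    min_prevalence <= prevalence_quartiles[1],
    max_prevalence >= prevalence_quartiles[3],
    target_event_rate > 0, target_event_rate < 1,
    signal_fraction >= 0, signal_fraction <= 1,
    effect_scale >= 0
  )
  structure(
    list(
      n_pop = as.integer(n_pop),
      p_binary = as.integer(p_binary),
      p_numeric = as.integer(p_numeric),
      prevalence_quartiles = prevalence_quartiles,
      min_prevalence = min_prevalence,
      max_prevalence = max_prevalence,
      target_event_rate = target_event_rate,
      signal_fraction = signal_fraction,
      effect_scale = effect_scale,
      effect_numeric = effect_numeric,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

# Quantile function of the prevalence law: piecewise log-linear through
# (0, min) - (.25, q1) - (.5, med) - (.75, q3) - (1, max). A single
# log-uniform cannot reproduce log-asymmetric quartiles; this is the minimal
# extension that matches all three anchor quartiles in expectation.
prevalence_quantile_fun <- function(config) {
  u_anchor <- c(0, 0.25, 0.5, 0.75, 1)
  lp <- log(c(
    config$min_prevalence, config$prevalence_quartiles, config$max_prevalence
  ))
  function(u) exp(stats::approx(u_anchor, lp, xout = u, rule = 2)$y)
}

#' Generate a synthetic plasmode population
#'
#' Draws predictor columns and the weakly predictable outcome `y_weak` from
#' the model described in [population_config()]. The strongly predictable
#' outcome `y_strong` is absent until [reinforce_population()] is applied.
#'
#' @param config a [population_config()].
#' @return an object of class `plasmode_population`: a list with elements
#'   `predictors` (numeric matrix, one named column per variable), `y_weak`
#'   (0/1 integer vector), `y_strong` (`NULL` here), `specs` (data frame with
#'   columns `name`, `kind`, `prevalence`, `effect`), `intercept` (solved
#'   log-odds intercept) and `seed`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  n <- config$n_pop
  pb <- config$p_binary
  pn <- config$p_numeric
  Q <- prevalence_quantile_fun(config)

  prev <- with_seed(
    derive_seed(config$seed, "prevalence"),
    Q(stats::runif(pb))
  )
  Xb <- with_seed(derive_seed(config$seed, "binary"), {
    vapply(prev, function(pr) stats::rbinom(n, 1L, pr), numeric(n))
  })
  colnames(Xb) <- sprintf("B%03d", seq_len(pb))

  if (pn > 0) {
    Xn <- with_seed(
      derive_seed(config$seed, "numeric"),
      matrix(stats::rnorm(n * pn), n, pn)
    )
    Xn <- scale(Xn)[, , drop = FALSE]
    colnames(Xn) <- sprintf("Z%02d", seq_len(pn))
    X <- cbind(Xb, Xn)
  } else {
    X <- Xb
  }

  n_signal <- round(config$signal_fraction * pb)
  beta <- numeric(ncol(X))
  names(beta) <- colnames(X)
  if (n_signal > 0) {
    idx <- order(prev, decreasing = TRUE)[seq_len(n_signal)]
    signs <- with_seed(
      derive_seed(config$seed, "signs"),
      sample(c(-1, 1), n_signal, replace = TRUE)
    )
    beta[idx] <- signs * config$effect_scale
  }
  if (pn > 0) beta[pb + seq_len(pn)] <- config$effect_numeric

  eta <- drop(X %*% beta)
  f <- function(b0) mean(expit(b0 + eta)) - config$target_event_rate
  sol <- tryCatch(
    stats::uniroot(f, interval = c(-30, 30), tol = 1e-10),
    error = function(e) {
      stop("could not solve for a finite intercept matching the target ",
           "event rate (pathological configuration): ", conditionMessage(e))
    }
  )
  b0 <- sol$root
  if (!is.finite(b0)) stop("intercept solution is non-finite")

  y_weak <- with_seed(
    derive_seed(config$seed, "outcome"),
    stats::rbinom(n, 1L, expit(b0 + eta))
  )

  specs <- data.frame(
    name = colnames(X),
    kind = c(rep("binary", pb), rep("numeric", pn)),
    prevalence = c(prev, rep(NA_real_, pn)),
    effect = unname(beta),
    stringsAsFactors = FALSE
  )

  pop <- structure(
    list(
      predictors = X,
      y_weak = as.integer(y_weak),
      y_strong = NULL,
      specs = specs,
      intercept = b0,
      seed = config$seed
    ),
    class = "plasmode_population"
  )
  validate_population(pop)
  pop
}

#' Validate a plasmode population object
#'
#' Checks the structural invariants: no missing values, outcomes coded 0/1,
#' one metadata row per predictor column, unique names, at least 4 rows.
#'
#' @param pop a `plasmode_population`.
#' @return `pop`, invisibly; stops on violation.
#' @export
validate_population <- function(pop) {
  stopifnot(inherits(pop, "plasmode_population"))
  X <- pop$predictors
  if (anyNA(X) || anyNA(pop$y_weak)) stop("population contains missing values")
  if (nrow(X) < 4) stop("population must have at least 4 rows")
  if (!all(pop$y_weak %in% c(0L, 1L))) stop("y_weak must be coded 0/1")
  if (!is.null(pop$y_strong)) {
    if (length(pop$y_strong) != nrow(X) || !all(pop$y_strong %in% c(0L, 1L))) {
      stop("y_strong must be a 0/1 vector with one entry per row")
    }
  }
  if (ncol(X) != nrow(pop$specs)) {
    stop("one metadata row is required per predictor column")
  }
  if (anyDuplicated(pop$specs$name)) stop("variable names must be unique")
  if (!identical(colnames(X), pop$specs$name)) {
    stop("column names must match the metadata in order")
  }
  bin <- pop$specs$kind == "binary"
  if (any(bin)) {
    vals <- X[, bin, drop = FALSE]
    if (!all(vals %in% c(0, 1))) stop("binary columns must contain only 0/1")
  }
  invisible(pop)
}

#' @export
print.plasmode_population <- function(x, ...) {
  nb <- sum(x$specs$kind == "binary")
  cat(sprintf(
    "plasmode population: %d individuals, %d predictors (%d binary, %d numeric)\n",
    nrow(x$predictors), ncol(x$predictors), nb, ncol(x$predictors) - nb
  ))
  cat(sprintf("  event rate y_weak: %.4f\n", mean(x$y_weak)))
  if (!is.null(x$y_strong)) {
    cat(sprintf("  event rate y_strong: %.4f\n", mean(x$y_strong)))
  } else {
    cat("  y_strong: not yet constructed\n")
  }
  invisible(x)
}

#' Quartiles of the realized binary prevalences
#'
#' Computes the first quartile, median and third quartile of the per-column
#' means over the binary predictor columns, using the linear-interpolation
#' (type 7) quantile convention.
#'
#' @param pop a `plasmode_population`.
#' @return named numeric vector `c(q1 = , median = , q3 = )`.
#' @export
empirical_prevalence_quartiles <- function(pop) {
  stopifnot(inherits(pop, "plasmode_population"))
  bin <- pop$specs$kind == "binary"
  if (!any(bin)) stop("population has no binary columns")
  m <- colMeans(pop$predictors[, bin, drop = FALSE])
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}
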