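#' Inverse-logit transform
#'
#' @param x numeric vector of log odds.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit transform
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return log odds.
#' @export
logit <- function(p) log(p / (1 - p))

#' Clip probabilities away from 0 and 1
#'
#' A single clipping constant is shared by every operation that takes a
#' logarithm or a logit of a predicted probability (cross-entropy,
#' calibration slope, outcome reinforcement), so that the measures remain
#' finite and mutually consistent.
#'
#' @param p numeric vector with values in \[0, 1\].
#' @param eps clipping constant; values are forced into \[eps, 1 - eps\].
#' @return clipped vector.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("probabilities must be finite and lie in [0, 1]")
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Derive a component seed deterministically
#'
#' Every stochastic component of a study (sampling, cross-validation folds,
#' forests, Bernoulli draws) derives its seed from the base seed plus a
#' trail of tags — scenario id, replication index, component name — via
#' integer mixing. Results are therefore reproducible and independent of
#' execution order, and no global RNG state leaks between components.
#'
#' @param base_seed integer base seed.
#' @param ... tags (integers or strings) identifying the component.
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(base_seed, ...) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L)
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(base_seed) %% m
  for (tag in list(...)) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    for (t in as.numeric(tag)) {
      h <- (h * 69069 + (t %% m) + 1) %% m
      h <- (h * 3935559000370003845 %% m + 2691343689449507681 %% m) %% m
    }
  }
  as.integer(h %% 2147483647L)
}

# Evaluate expr under a local RNG state; the caller's .Random.seed is
# untouched (no global-state leakage between components).
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
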