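#' Configuration for the outcome-reinforcement procedure
#'
#' The strongly predictable outcome is constructed semi-synthetically:
#' out-of-fold probability-forest predictions of the weak outcome are
#' transformed to log odds, multiplied by a constant (default 3.5), back
#' transformed, and used as Bernoulli parameters for a fresh outcome draw.
#'
#' @param n_folds number of disjoint folds for the out-of-fold predictions.
#' @param constant positive multiplier applied to the predicted log odds.
#' @param seed integer seed (fold assignment and Bernoulli draws).
#' @param forest a [forest_params()] for the fold-wise forests.
#' @return an object of class `reinforcement_config`.
#' @export
reinforcement_config <- function(n_folds = 4, constant = 3.5, seed = 1L,
                                 forest = forest_params()) {
  stopifnot(n_folds >= 2, constant > 0, inherits(forest, "forest_params"))
  structure(
    list(n_folds = as.integer(n_folds), constant = constant,
         seed = as.integer(seed), forest = forest),
    class = "reinforcement_config"
  )
}

#' Out-of-fold forest probabilities for the weak outcome
#'
#' Randomly partitions the population into `n_folds` approximately equal
#' disjoint subsets; for each, trains a probability forest on the remaining
#' folds with all predictor variables and predicts the held-out rows. Every
#' row therefore receives one prediction from a forest that never saw it.
#'
#' @param pop a `plasmode_population` with `y_weak` present.
#' @param cfg a [reinforcement_config()].
#' @return numeric vector of probabilities, one per population row, clipped
#'   into (0, 1); the fold assignment is attached as attribute `"fold"`.
#' @export
outoffold_probabilities <- function(pop, cfg = reinforcement_config()) {
  validate_population(pop)
  stopifnot(inherits(cfg, "reinforcement_config"))
  n <- nrow(pop$predictors)
  if (n < cfg$n_folds) stop("population smaller than the number of folds")
  fold <- with_seed(
    derive_seed(cfg$seed, "folds"),
    sample(rep(seq_len(cfg$n_folds), length.out = n))
  )
  if (any(tabulate(fold, cfg$n_folds) == 0)) stop("empty fold")
  p <- numeric(n)
  for (k in seq_len(cfg$n_folds)) {
    test <- fold == k
    ytr <- pop$y_weak[!test]
    if (length(unique(pop$y_weak[test])) < 2) {
      warning("held-out fold ", k, " contains a single outcome class")
    }
    fp <- cfg$forest
    fp$seed <- derive_seed(cfg$seed, "forest", k)
    model <- train_probability_forest(
      pop$predictors[!test, , drop = FALSE], ytr, fp
    )
    p[test] <- predict(model, pop$predictors[test, , drop = FALSE])
  }
  p <- clip_prob(p)
  attr(p, "fold") <- fold
  p
}

#' Reinforce predicted probabilities
#'
#' Transforms probabilities to log odds, multiplies by `constant`, and back
#' transforms: `expit(constant * logit(p))`. The map is strictly increasing
#' with fixed point 0.5; for `constant > 1` it pushes probabilities away
#' from 0.5, strengthening the predictor-outcome association when outcomes
#' are redrawn from the result. Inputs at exactly 0 or 1 are clipped to
#' `[1e-6, 1 - 1e-6]` first, since their log odds are not finite.
#'
#' @param p probability vector in \[0, 1\].
#' @param constant positive multiplier on the log-odds scale.
#' @return reinforced probability vector.
#' @export
reinforce_probabilities <- function(p, constant = 3.5) {
  stopifnot(is.numeric(constant), length(constant) == 1, constant > 0)
  expit(constant * logit(clip_prob(p)))
}

#' Sample a reinforced binary outcome
#'
#' Independent Bernoulli draws with the reinforced probabilities as
#' parameters; deterministic given the seed.
#'
#' @param p_reinforced probability vector in \[0, 1\].
#' @param seed integer seed.
#' @return 0/1 integer vector.
#' @export
sample_strong_outcome <- function(p_reinforced, seed = 1L) {
  if (any(!is.finite(p_reinforced)) || any(p_reinforced < 0) ||
      any(p_reinforced > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  with_seed(
    derive_seed(seed, "bernoulli"),
    stats::rbinom(length(p_reinforced), 1L, p_reinforced)
  )
}

#' Construct the strongly predictable outcome for a population
#'
#' Runs the full reinforcement pipeline — out-of-fold forest predictions,
#' log-odds scaling, Bernoulli redraw — once, and freezes the result as
#' `y_strong` on the population. All scenario subsamples reuse this single
#' `y_strong`: strong predictability is a property of the population, not of
#' a replication.
#'
#' @param pop a `plasmode_population`.
#' @param cfg a [reinforcement_config()].
#' @return the population with `y_strong` filled in and a `reinforcement`
#'   element recording the out-of-fold probabilities, their AUROC against
#'   `y_weak`, and the realized strong event rate.
#' @export
reinforce_population <- function(pop, cfg = reinforcement_config()) {
  p_oof <- outoffold_probabilities(pop, cfg)
  p_strong <- reinforce_probabilities(as.numeric(p_oof), cfg$constant)
  y_strong <- sample_strong_outcome(p_strong, seed = cfg$seed)
  pop$y_strong <- as.integer(y_strong)
  pop$reinforcement <- list(
    constant = cfg$constant,
    n_folds = cfg$n_folds,
    oof_probabilities = as.numeric(p_oof),
    oof_auroc_weak = auroc(as.numeric(p_oof), pop$y_weak),
    strong_event_rate = mean(y_strong)
  )
  validate_population(pop)
  pop
}
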