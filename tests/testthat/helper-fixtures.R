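# Shared fixtures and independent oracles, all built in code at test time.

# O(n^2) pairwise AUROC oracle: ties count one half. Deliberately brute
# force and independent of the rank-based implementation it checks.
auroc_bruteforce <- function(p, y) {
  ev <- p[y == 1]
  ne <- p[y == 0]
  tot <- 0
  for (a in ev) for (b in ne) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}

# Small, dense population for fast unit tests: moderate prevalences so
# degeneracy is rare, a handful of clear signal columns.
tiny_population <- function(n_pop = 1500, p_binary = 40, seed = 11,
                            effect_scale = 0.8, signal_fraction = 0.1) {
  generate_population(population_config(
    n_pop = n_pop, p_binary = p_binary, p_numeric = 2,
    prevalence_quartiles = c(0.05, 0.15, 0.35),
    min_prevalence = 0.02, max_prevalence = 0.5,
    target_event_rate = 0.558,
    signal_fraction = signal_fraction, effect_scale = effect_scale,
    effect_numeric = 0.4, seed = seed
  ))
}

# Hand-built study sample from explicit columns.
sample_from_cols <- function(..., y) {
  cols <- list(...)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  study_sample(X, y)
}

# Crafted selection results for exercising the fallback ladder.
make_selection <- function(method, vars, coefs = NULL, intercept = 0) {
  coefs <- coefs %||% stats::setNames(rep(1, length(vars)), vars)
  plasmodeRF:::new_selection_result(method, vars, intercept, coefs,
                                    n_candidates = max(10, length(vars)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

fast_forest <- function(seed = 1L) forest_params(n_trees = 60, seed = seed)

# The desk-scale reinforced population used by the directional acceptance
# checks; built once per test run and cached.
.study_cache <- new.env(parent = emptyenv())
study_population <- function() {
  if (is.null(.study_cache$pop)) {
    pop <- generate_population(population_config(seed = 20260925))
    .study_cache$pop <- reinforce_population(
      pop, reinforcement_config(seed = 20260925)
    )
  }
  .study_cache$pop
}
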