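current_sample <- function(vars = c("A", "B", "C", "D"), n = 40, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * length(vars), 1, 0.4), n, length(vars),
              dimnames = list(NULL, vars))
  study_sample(X, rep(c(0L, 1L), n / 2))
}

test_that("strategy sets follow the set algebra of the five methods", {
  cur <- current_sample()
  L <- make_selection("lasso", c("A", "B"))
  U <- make_selection("univariate", c("B", "C"))
  expect_setequal(build_strategy_set("M1", L, U, cur)$variables,
                  c("A", "B", "C", "D"))
  expect_setequal(build_strategy_set("M2", L, U, cur)$variables, c("A", "B"))
  expect_equal(build_strategy_set("M3", L, U, cur)$variables, "B")
  expect_setequal(build_strategy_set("M4", L, U, cur)$variables,
                  c("A", "B", "C"))
  expect_equal(build_strategy_set("M2", L, U, cur)$fallback, "none")
  expect_error(build_strategy_set("M9", L, U, cur), "unknown method")
})

test_that("all four fallback rules resolve empty selections", {
  cur <- current_sample()
  empty <- make_selection("lasso", character(0))
  L <- make_selection("lasso", c("A", "B"))
  U <- make_selection("univariate", c("C"))

  m2 <- build_strategy_set("M2", empty, U, cur)
  expect_setequal(m2$variables, cur$nondegenerate)
  expect_equal(m2$fallback, "all-variables")

  # disjoint selections: M3's intersection is empty -> M4's union
  m3 <- build_strategy_set("M3", L, U, cur)
  expect_setequal(m3$variables, c("A", "B", "C"))
  expect_equal(m3$fallback, "union-substitute")

  m4 <- build_strategy_set("M4", empty, empty, cur)
  expect_setequal(m4$variables, cur$nondegenerate)
  expect_equal(m4$fallback, "all-variables")

  m5 <- build_strategy_set("M5", empty, U, cur)
  expect_equal(m5$variables, "C")
  expect_equal(m5$fallback, "other-model")
  expect_equal(m5$m5_winner, "univariate")

  m5b <- build_strategy_set("M5", empty, empty, cur)
  expect_setequal(m5b$variables, cur$nondegenerate)
  expect_equal(m5b$fallback, "both-empty-all")

  # both selections empty cascades M3 all the way to all variables
  m3b <- build_strategy_set("M3", empty, empty, cur)
  expect_setequal(m3b$variables, cur$nondegenerate)
  expect_equal(m3b$fallback, "all-variables")
})

test_that("variables degenerate in the current sample are removed first", {
  X <- cbind(A = rep(0L, 20), B = rbinom(20, 1, 0.5), C = rbinom(20, 1, 0.5))
  cur <- study_sample(X, rep(c(0L, 1L), 10))
  L <- make_selection("lasso", "A") # only a degenerate variable
  U <- make_selection("univariate", c("B"))
  m2 <- build_strategy_set("M2", L, U, cur)
  expect_setequal(m2$variables, c("B", "C"))
  expect_equal(m2$fallback, "all-variables")
  m5 <- build_strategy_set("M5", L, U, cur)
  expect_equal(m5$variables, "B")
  expect_equal(m5$fallback, "other-model")
})

test_that("set-algebra invariants hold across random selection draws", {
  cur <- current_sample(vars = paste0("V", 1:12), n = 60)
  set.seed(77)
  for (i in 1:20) {
    L <- make_selection("lasso", sample(cur$nondegenerate, sample(0:6, 1)))
    U <- make_selection("univariate", sample(cur$nondegenerate, sample(0:6, 1)))
    m2 <- build_strategy_set("M2", L, U, cur)
    m3 <- build_strategy_set("M3", L, U, cur)
    m4 <- build_strategy_set("M4", L, U, cur)
    if (m3$fallback == "none" && m2$fallback == "none") {
      expect_true(all(m3$variables %in% m2$variables))
    }
    if (m3$fallback == "none" && m4$fallback == "none") {
      expect_true(all(m3$variables %in% m4$variables))
    }
    expect_true(all(m2$variables %in% cur$nondegenerate))
    if (m4$fallback == "none") {
      expect_setequal(m4$variables, union(L$selected, U$selected))
    }
  }
})

test_that("m5 winner is chosen by unchanged-model AUROC, ties to lasso", {
  cur <- current_sample(vars = c("S", "N1", "N2"), n = 200, seed = 3)
  # outcome driven by S
  set.seed(4)
  y <- rbinom(200, 1, plogis(-1 + 2 * cur$X[, "S"]))
  cur <- study_sample(cur$X, y)
  good <- make_selection("lasso", "S", coefs = c(S = 2), intercept = -1)
  noise <- make_selection("univariate", "N1", coefs = c(N1 = 0.1), intercept = 0)
  expect_equal(m5_pick_winner(good, noise, cur), "lasso")
  expect_equal(m5_pick_winner(noise, good, cur), "univariate")
  # identical models tie; tie goes to the lasso
  same <- make_selection("univariate", "S", coefs = c(S = 2), intercept = -1)
  expect_equal(m5_pick_winner(good, same, cur), "lasso")
})

test_that("the true-model preceding study wins M5 with high frequency", {
  wins <- vapply(1:15, function(s) {
    set.seed(400 + s)
    X <- cbind(S = rbinom(1000, 1, 0.3), N = rbinom(1000, 1, 0.3))
    y <- rbinom(1000, 1, plogis(-0.5 + 1.2 * X[, "S"]))
    cur <- study_sample(X, y)
    truth <- make_selection("univariate", "S", coefs = c(S = 1.2),
                            intercept = -0.5)
    junk <- make_selection("lasso", "N", coefs = c(N = 0.8), intercept = 0)
    m5_pick_winner(junk, truth, cur) == "univariate"
  }, logical(1))
  expect_gt(mean(wins), 0.95)
})

test_that("probability forest honors its contract", {
  pop <- tiny_population(n_pop = 700, p_binary = 15, effect_scale = 1.2,
                         seed = 31)
  X <- pop$predictors[1:400, ]
  y <- pop$y_weak[1:400]
  expect_error(train_probability_forest(X, rep(1L, 400)), "single class")
  expect_error(train_probability_forest(X[, 0, drop = FALSE], y),
               "at least one predictor")

  f1 <- train_probability_forest(X, y, forest_params(n_trees = 80, seed = 5))
  f2 <- train_probability_forest(X, y, forest_params(n_trees = 80, seed = 5))
  newX <- pop$predictors[401:700, ]
  p1 <- predict(f1, newX)
  p2 <- predict(f2, newX)
  expect_identical(p1, p2) # determinism given the seed
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_lt(abs(mean(predict(f1, X)) - mean(y)), 0.1)
})

test_that("a single binary predictor's forest AUROC equals its own concordance", {
  set.seed(16)
  x <- rbinom(600, 1, 0.4)
  y <- rbinom(600, 1, plogis(-1 + 2 * x))
  X <- cbind(S = x)
  fit <- train_probability_forest(X[1:400, , drop = FALSE], y[1:400],
                                  forest_params(n_trees = 100, seed = 1))
  xv <- X[401:600, , drop = FALSE]
  yv <- y[401:600]
  p <- predict(fit, xv)
  # predictions are a monotone function of the lone predictor, so the AUROC
  # is exactly the predictor's concordance
  expect_equal(auroc(p, yv), auroc(xv[, "S"], yv), tolerance = 1e-12)
})

test_that("the lasso comparator shares the preceding-study implementation", {
  pop <- tiny_population(n_pop = 400, p_binary = 12, seed = 6)
  s <- drop_degenerate(study_sample(pop$predictors, pop$y_weak))
  a <- fit_lasso_comparator(s, seed = 11)
  b <- fit_lasso_study(s, n_cv_folds = 10, seed = 11)
  expect_identical(a$selected, b$selected)
  expect_identical(a$coefficients, b$coefficients)
})

test_that("mtry and node-size rules resolve correctly", {
  expect_equal(plasmodeRF:::resolve_mtry(forest_params(), 400), 20)
  expect_equal(plasmodeRF:::resolve_mtry(
    forest_params(mtry_rule = "fixed", mtry_value = 7), 5), 5)
  expect_equal(plasmodeRF:::resolve_mtry(
    forest_params(mtry_rule = "fraction", mtry_value = 0.25), 40), 10)
  # the 10% minimum-node-size variant
  expect_equal(plasmodeRF:::resolve_min_node_size(
    forest_params(min_node_size = 0.1), 250), 25)
  expect_equal(plasmodeRF:::resolve_min_node_size(forest_params(), 250), 10)
})
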