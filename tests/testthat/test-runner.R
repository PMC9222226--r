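runner_population <- function() {
  if (is.null(.study_cache$runner_pop)) {
    pop <- tiny_population(n_pop = 2600, p_binary = 30, seed = 51,
                           effect_scale = 1.0)
    .study_cache$runner_pop <- reinforce_population(
      pop, reinforcement_config(seed = 51, forest = fast_forest())
    )
  }
  .study_cache$runner_pop
}

test_that("replication samples are disjoint, sized and deterministic", {
  pop <- runner_population()
  scn <- scenario(200, "weak", n_replications = 2, validation_size = 800,
                  base_seed = 9)
  s <- draw_replication_samples(pop, scn, 1)
  idx <- attr(s, "indices")
  expect_equal(lengths(idx), c(`1` = 200, `2` = 200, `3` = 200, `4` = 800))
  expect_equal(length(unique(unlist(idx))), 1400) # pairwise disjoint
  s2 <- draw_replication_samples(pop, scn, 1)
  expect_identical(attr(s2, "indices"), idx)
  s3 <- draw_replication_samples(pop, scn, 2)
  expect_false(identical(attr(s3, "indices"), idx))
  # strong arm picks the reinforced outcome
  scn_s <- scenario(200, "strong", validation_size = 800, base_seed = 9)
  ss <- draw_replication_samples(pop, scn_s, 1)
  i1 <- attr(ss, "indices")[[1]]
  expect_identical(ss$preceding1$y, pop$y_strong[i1])

  bare <- generate_population(population_config(
    n_pop = 1500, p_binary = 10, prevalence_quartiles = c(0.1, 0.2, 0.3),
    min_prevalence = 0.05, seed = 1
  ))
  expect_error(draw_replication_samples(bare, scn_s, 1), "reinforce")
})

test_that("infeasible scenarios fail before any work", {
  pop <- runner_population()
  scn <- scenario(1000, "weak", validation_size = 2000, base_seed = 1)
  expect_error(run_study(pop, scn), "infeasible")
})

test_that("a replication yields one record per method with sane values", {
  pop <- runner_population()
  scn <- scenario(150, "weak", validation_size = 600, base_seed = 31)
  out <- run_replication(pop, scn, 1, forest = fast_forest())
  expect_setequal(out$records$method, c("LASSO", "M1", "M2", "M3", "M4", "M5"))
  expect_equal(nrow(out$records), 6)
  expect_true(all(is.na(out$records$error)))
  expect_true(all(out$records$auroc >= 0 & out$records$auroc <= 1))
  expect_true(all(out$records$cross_entropy >=
                    out$records$max_ce_contribution))
  d <- out$descriptives
  expect_lte(d$n_intersection, min(d$n_lasso, d$n_univariate))
  expect_lte(max(d$n_lasso, d$n_univariate), d$n_union)
  expect_lte(d$n_union, d$n_lasso + d$n_univariate)
})

test_that("identical variable sets with a shared forest seed give identical records", {
  pop <- runner_population()
  scn <- scenario(150, "weak", validation_size = 600, base_seed = 31)
  samples <- draw_replication_samples(pop, scn, 1)
  cur_f <- drop_degenerate(samples$current)
  sel <- make_selection("lasso", cur_f$nondegenerate[1:5])
  m2 <- build_strategy_set("M2", sel, sel, samples$current)
  m3 <- build_strategy_set("M3", sel, sel, samples$current)
  expect_setequal(m2$variables, m3$variables)
  fp <- fast_forest(seed = 123)
  f2 <- train_probability_forest(cur_f$X[, sort(m2$variables)], cur_f$y, fp)
  f3 <- train_probability_forest(cur_f$X[, sort(m3$variables)], cur_f$y, fp)
  expect_identical(predict(f2, samples$validation$X),
                   predict(f3, samples$validation$X))
})

test_that("run_study aggregates, conserves records and is reproducible", {
  pop <- runner_population()
  scns <- list(
    scenario(120, "weak", n_replications = 3, validation_size = 500,
             base_seed = 77),
    scenario(120, "strong", n_replications = 3, validation_size = 500,
             base_seed = 77)
  )
  res <- run_study(pop, scns, forest = fast_forest())
  expect_equal(nrow(res$records), 2 * 3 * 6) # scenarios x reps x methods
  expect_equal(nrow(res$performance), 2 * 6)
  expect_equal(nrow(res$selection), 2)
  expect_true(all(res$performance$sd_auroc >= 0, na.rm = TRUE))

  res2 <- run_study(pop, scns, forest = fast_forest())
  expect_identical(res$records, res2$records)
})

test_that("selection counts grow with sample size under signal", {
  pop <- runner_population()
  mean_sel <- vapply(c(120, 400), function(n) {
    scn <- scenario(n, "strong", n_replications = 4, validation_size = 400,
                    base_seed = 13)
    cnt <- vapply(1:4, function(r) {
      s <- draw_replication_samples(pop, scn, r)
      sel <- fit_lasso_study(drop_degenerate(s$preceding1),
                             seed = derive_seed(13, "t", n, r))
      length(sel$selected)
    }, numeric(1))
    mean(cnt)
  }, numeric(1))
  expect_lte(mean_sel[1], mean_sel[2])
})

test_that("aggregation reproduces hand-computed summaries", {
  rec <- data.frame(
    scenario = "weak_n100", predictability = "weak", sample_size = 100,
    replication = 1:3, method = "M1",
    auroc = c(0.6, 0.7, 0.8), brier = c(0.2, 0.25, 0.3),
    cal_slope = c(exp(1), exp(-1), 1),
    cross_entropy = c(100, 110, 120), max_ce_contribution = c(1, 2, 3),
    n_variables = 5L, fallback = "none", m5_winner = NA_character_,
    error = NA_character_, stringsAsFactors = FALSE
  )
  agg <- aggregate_performance(rec)
  expect_equal(agg$mean_auroc, 0.7)
  expect_equal(agg$sd_auroc, sd(c(0.6, 0.7, 0.8)))
  expect_equal(agg$mse_log_slope, mean(c(1, 1, 0)))
  expect_equal(agg$mean_cross_entropy, 110)
  expect_equal(agg$mean_max_ce_contribution, 2)
  expect_equal(agg$n_slope_excluded, 0)

  rec$auroc <- 0.65
  rec$cal_slope <- c(2, -1, NA) # non-positive and non-finite slopes excluded
  agg2 <- aggregate_performance(rec)
  expect_equal(agg2$sd_auroc, 0)
  expect_equal(agg2$mean_cal_slope, 2)
  expect_equal(agg2$n_slope_excluded, 2)
})

test_that("derived seeds stay within 32-bit range and separate components", {
  seeds <- c(
    derive_seed(1, "a"), derive_seed(1, "b"), derive_seed(2, "a"),
    derive_seed(1, "a", 1), derive_seed(1, "a", 2),
    derive_seed(2147483000, "draw", "strong_n4000", 1000, 5)
  )
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_equal(anyDuplicated(seeds), 0)
  expect_identical(derive_seed(1, "a", 1), derive_seed(1, "a", 1))
})
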