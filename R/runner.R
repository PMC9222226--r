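#' Define one simulation scenario
#'
#' One cell of the scenario grid: a common sample size for the two preceding
#' studies and the current study, a predictability arm selecting which
#' outcome column is predicted, a replication count, and the validation-set
#' size redrawn at every replication.
#'
#' @param sample_size size of each of the three study samples.
#' @param predictability `"weak"` (original outcome) or `"strong"`
#'   (reinforced outcome).
#' @param n_replications number of independent replications.
#' @param validation_size size of the validation sample.
#' @param base_seed integer seed from which every per-replication,
#'   per-component seed is derived.
#' @return an object of class `scenario`.
#' @export
scenario <- function(sample_size, predictability = c("weak", "strong"),
                     n_replications = 100, validation_size = 2000,
                     base_seed = 1L) {
  predictability <- match.arg(predictability)
  stopifnot(sample_size >= 10, n_replications >= 1, validation_size >= 10)
  structure(
    list(
      sample_size = as.integer(sample_size),
      predictability = predictability,
      n_replications = as.integer(n_replications),
      validation_size = as.integer(validation_size),
      base_seed = as.integer(base_seed),
      id = sprintf("%s_n%d", predictability, sample_size)
    ),
    class = "scenario"
  )
}

#' Build the full scenario grid
#'
#' Crosses the sample sizes with the two predictability arms. The reference
#' grid uses sample sizes 4000, 2000, 1000, 500 and 250 with validation size
#' 10,000 and 1000 replications; the defaults here are a desk-scale profile.
#'
#' @param sample_sizes vector of sample sizes.
#' @param predictability arms to include.
#' @inheritParams scenario
#' @return list of [scenario()] objects.
#' @export
scenario_grid <- function(sample_sizes = c(1000, 500, 250),
                          predictability = c("weak", "strong"),
                          n_replications = 100, validation_size = 2000,
                          base_seed = 1L) {
  out <- list()
  for (arm in predictability) {
    for (n in sample_sizes) {
      out[[length(out) + 1L]] <- scenario(
        n, arm, n_replications, validation_size, base_seed
      )
    }
  }
  out
}

scenario_outcome <- function(pop, scn) {
  if (scn$predictability == "weak") {
    pop$y_weak
  } else {
    if (is.null(pop$y_strong)) {
      stop("scenario requires the reinforced outcome; run reinforce_population() first")
    }
    pop$y_strong
  }
}

check_feasible <- function(pop, scn) {
  need <- 3L * scn$sample_size + scn$validation_size
  if (need > nrow(pop$predictors)) {
    stop("infeasible scenario '", scn$id, "': needs ", need,
         " disjoint rows but the population has ", nrow(pop$predictors))
  }
  invisible(TRUE)
}

#' Draw the four disjoint samples for one replication
#'
#' Draws, without replacement and mutually disjoint, the two preceding-study
#' samples, the current-study sample (all of size `scenario$sample_size`)
#' and the validation sample, from the population. Disjointness prevents
#' information leaking between the "studies". If any drawn sample has a
#' single outcome class the draw is retried (up to 5 times, each with its
#' own derived seed) before failing.
#'
#' @param pop a `plasmode_population`.
#' @param scn a [scenario()].
#' @param rep_index replication index (1-based).
#' @return named list of four [study_sample()]s: `preceding1`, `preceding2`,
#'   `current`, `validation`; row indices attached as attribute `"indices"`.
#' @export
draw_replication_samples <- function(pop, scn, rep_index) {
  validate_population(pop)
  check_feasible(pop, scn)
  y_all <- scenario_outcome(pop, scn)
  n <- scn$sample_size
  v <- scn$validation_size
  sizes <- c(n, n, n, v)
  for (attempt in 1:5) {
    idx <- with_seed(
      derive_seed(scn$base_seed, "draw", scn$id, rep_index, attempt),
      sample.int(nrow(pop$predictors), sum(sizes))
    )
    splits <- split(idx, rep(1:4, times = sizes))
    ok <- all(vapply(splits, function(i) length(unique(y_all[i])) == 2,
                     logical(1)))
    if (ok) {
      out <- list(
        preceding1 = study_sample(pop$predictors[splits[[1]], , drop = FALSE],
                                  y_all[splits[[1]]]),
        preceding2 = study_sample(pop$predictors[splits[[2]], , drop = FALSE],
                                  y_all[splits[[2]]]),
        current = study_sample(pop$predictors[splits[[3]], , drop = FALSE],
                               y_all[splits[[3]]]),
        validation = study_sample(pop$predictors[splits[[4]], , drop = FALSE],
                                  y_all[splits[[4]]])
      )
      attr(out, "indices") <- splits
      return(out)
    }
  }
  stop("replication ", rep_index, " of scenario '", scn$id,
       "': single-class sample in 5 consecutive draws")
}

method_labels <- function() c("LASSO", "M1", "M2", "M3", "M4", "M5")

flagged_record <- function(scn, rep_index, method, msg) {
  data.frame(
    scenario = scn$id, predictability = scn$predictability,
    sample_size = scn$sample_size, replication = rep_index, method = method,
    auroc = NA_real_, brier = NA_real_, cal_slope = NA_real_,
    cross_entropy = NA_real_, max_ce_contribution = NA_real_,
    n_variables = NA_integer_, fallback = NA_character_,
    m5_winner = NA_character_, error = msg,
    stringsAsFactors = FALSE
  )
}

#' Run one replication of one scenario
#'
#' Draws the four samples, fits the two preceding studies (cross-validated
#' Lasso; univariate selection) on their own samples, resolves the M1-M5
#' candidate sets with the fallback ladder, trains one probability forest
#' per strategy plus the current-study Lasso comparator, and evaluates all
#' six prediction vectors on the validation sample. The same derived forest
#' seed is used for every strategy within a replication, so strategies whose
#' variable sets coincide produce identical forests.
#'
#' A failure inside one method yields a flagged (all-`NA`) record for that
#' method rather than aborting the replication.
#'
#' @param pop a `plasmode_population` (reinforced if the scenario uses the
#'   strong arm).
#' @param scn a [scenario()].
#' @param rep_index replication index.
#' @param forest a [forest_params()] template (its seed is re-derived).
#' @param methods subset of `c("LASSO", "M1", ..., "M5")` to run.
#' @return list with `records` (one data-frame row per method) and
#'   `descriptives` (one row: non-degenerate and selected-variable counts).
#' @export
run_replication <- function(pop, scn, rep_index, forest = forest_params(),
                            methods = method_labels()) {
  stopifnot(all(methods %in% method_labels()))
  samples <- draw_replication_samples(pop, scn, rep_index)
  cur_f <- drop_degenerate(samples$current)
  p1_f <- drop_degenerate(samples$preceding1)
  p2_f <- drop_degenerate(samples$preceding2)

  sel_lasso <- fit_lasso_study(
    p1_f, seed = derive_seed(scn$base_seed, "lasso1", scn$id, rep_index)
  )
  sel_uni <- fit_univariate_study(p2_f)

  Xval <- samples$validation$X
  yval <- samples$validation$y
  forest_seed <- derive_seed(scn$base_seed, "forest", scn$id, rep_index)

  records <- list()
  for (m in methods) {
    rec <- tryCatch({
      if (m == "LASSO") {
        comp <- fit_lasso_comparator(
          cur_f,
          seed = derive_seed(scn$base_seed, "lassoC", scn$id, rep_index)
        )
        p <- predict_logistic(comp, Xval)
        nvar <- length(comp$selected)
        fb <- NA_character_
        winner <- NA_character_
      } else {
        set <- build_strategy_set(m, sel_lasso, sel_uni, samples$current)
        fp <- forest
        fp$seed <- forest_seed
        fit <- train_probability_forest(
          cur_f$X[, set$variables, drop = FALSE], cur_f$y, fp
        )
        p <- predict(fit, Xval)
        nvar <- length(set$variables)
        fb <- set$fallback
        winner <- set$m5_winner
      }
      cbind(
        data.frame(scenario = scn$id, predictability = scn$predictability,
                   sample_size = scn$sample_size, replication = rep_index,
                   method = m, stringsAsFactors = FALSE),
        evaluate_predictions(p, yval),
        data.frame(n_variables = nvar, fallback = fb, m5_winner = winner,
                   error = NA_character_, stringsAsFactors = FALSE)
      )
    }, error = function(e) {
      flagged_record(scn, rep_index, m, conditionMessage(e))
    })
    records[[m]] <- rec
  }

  descriptives <- data.frame(
    scenario = scn$id, predictability = scn$predictability,
    sample_size = scn$sample_size, replication = rep_index,
    n_nondegenerate = length(samples$current$nondegenerate),
    n_lasso = length(sel_lasso$selected),
    n_univariate = length(sel_uni$selected),
    n_union = length(union(sel_lasso$selected, sel_uni$selected)),
    n_intersection = length(intersect(sel_lasso$selected, sel_uni$selected)),
    stringsAsFactors = FALSE
  )
  list(records = do.call(rbind, records), descriptives = descriptives)
}

#' Run the full simulation study
#'
#' Loops scenarios and replications, collecting one performance record per
#' replication and method plus per-replication descriptive counts, and
#' aggregates them into the summary tables. Every stochastic component
#' derives its seed from `(base_seed, scenario id, replication, component)`,
#' so results are reproducible and independent of execution order. If
#' `out_dir` is given, tidy records, aggregate tables and a run manifest are
#' written there as delimited text/JSON.
#'
#' @param pop a `plasmode_population`.
#' @param scenarios list of [scenario()]s (e.g. from [scenario_grid()]).
#' @param forest a [forest_params()] template.
#' @param methods methods to run (see [run_replication()]).
#' @param out_dir optional output directory.
#' @param verbose print progress.
#' @return object of class `study_result`: list with `records`,
#'   `descriptives`, `performance` (aggregate means/SDs, MSE of log slope),
#'   `selection` (selected-count summaries) and `manifest`.
#' @export
run_study <- function(pop, scenarios, forest = forest_params(),
                      methods = method_labels(), out_dir = NULL,
                      verbose = FALSE) {
  validate_population(pop)
  if (inherits(scenarios, "scenario")) scenarios <- list(scenarios)
  for (scn in scenarios) check_feasible(pop, scn)

  all_rec <- list()
  all_desc <- list()
  for (scn in scenarios) {
    for (r in seq_len(scn$n_replications)) {
      if (verbose && r %% 25 == 0) {
        message(scn$id, ": replication ", r, "/", scn$n_replications)
      }
      out <- run_replication(pop, scn, r, forest = forest, methods = methods)
      all_rec[[paste(scn$id, r)]] <- out$records
      all_desc[[paste(scn$id, r)]] <- out$descriptives
    }
  }
  records <- do.call(rbind, all_rec)
  rownames(records) <- NULL
  descriptives <- do.call(rbind, all_desc)
  rownames(descriptives) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("plasmodeRF")),
    n_pop = nrow(pop$predictors),
    p = ncol(pop$predictors),
    population_seed = pop$seed,
    scenarios = lapply(scenarios, function(s) s[c(
      "id", "sample_size", "predictability", "n_replications",
      "validation_size", "base_seed"
    )]),
    forest = unclass(forest)[c("n_trees", "mtry_rule", "min_node_size")],
    methods = methods,
    n_failed_records = sum(!is.na(records$error)),
    slope_exclusions = sum(!is.finite(records$cal_slope))
  )

  res <- structure(
    list(
      records = records,
      descriptives = descriptives,
      performance = aggregate_performance(records),
      selection = aggregate_selection(descriptives),
      manifest = manifest
    ),
    class = "study_result"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tidy <- function(df, name) {
      num <- vapply(df, is.double, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
      utils::write.table(df, file.path(out_dir, name), sep = ",",
                         row.names = FALSE, quote = FALSE)
    }
    write_tidy(records, "records.csv")
    write_tidy(descriptives, "descriptives.csv")
    write_tidy(res$performance, "aggregate_performance.csv")
    write_tidy(res$selection, "aggregate_selection.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat("plasmode simulation study result\n")
  cat(sprintf("  %d records (%d scenarios x methods x replications)\n",
              nrow(x$records), length(unique(x$records$scenario))))
  cat(sprintf("  failed records: %d; slope exclusions: %d\n",
              x$manifest$n_failed_records, x$manifest$slope_exclusions))
  print(utils::head(x$performance, 12))
  invisible(x)
}

#' Aggregate per-replication performance records
#'
#' Per (scenario, method): means and SDs of AUROC, Brier score, calibration
#' slope and cross-entropy; the mean squared log calibration slope; the mean
#' maximum cross-entropy contribution; and the number of replications whose
#' slope was excluded as non-finite or non-positive.
#'
#' @param records the `records` data frame of a [run_study()] result.
#' @return data frame, one row per scenario and method.
#' @export
aggregate_performance <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  keys <- unique(records[c("scenario", "predictability", "sample_size",
                           "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- records[records$scenario == keys$scenario[i] &
                     records$method == keys$method[i], ]
    sl <- sub$cal_slope
    ok <- is.finite(sl) & sl > 0
    msl <- if (any(ok)) mean(log(sl[ok])^2) else NA_real_
    data.frame(
      keys[i, ],
      n_replications = nrow(sub),
      mean_auroc = mean(sub$auroc, na.rm = TRUE),
      sd_auroc = stats::sd(sub$auroc, na.rm = TRUE),
      mean_brier = mean(sub$brier, na.rm = TRUE),
      sd_brier = stats::sd(sub$brier, na.rm = TRUE),
      mean_cal_slope = mean(sl[ok]),
      sd_cal_slope = stats::sd(sl[ok]),
      mse_log_slope = msl,
      n_slope_excluded = sum(!ok),
      mean_cross_entropy = mean(sub$cross_entropy, na.rm = TRUE),
      sd_cross_entropy = stats::sd(sub$cross_entropy, na.rm = TRUE),
      mean_max_ce_contribution = mean(sub$max_ce_contribution, na.rm = TRUE),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$predictability, -out$sample_size, out$method), ]
}

#' Aggregate selection descriptives
#'
#' Per scenario: mean (min, max) number of non-degenerate current-study
#' variables and mean (min, max) numbers of variables selected by the Lasso,
#' by univariate selection, and by their union and intersection.
#'
#' @param descriptives the `descriptives` data frame of a [run_study()]
#'   result.
#' @return data frame, one row per scenario.
#' @export
aggregate_selection <- function(descriptives) {
  stopifnot(is.data.frame(descriptives), nrow(descriptives) > 0)
  keys <- unique(descriptives[c("scenario", "predictability", "sample_size")])
  summ <- function(x) c(mean(x), min(x), max(x))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- descriptives[descriptives$scenario == keys$scenario[i], ]
    vals <- c(
      summ(sub$n_nondegenerate), summ(sub$n_lasso), summ(sub$n_univariate),
      summ(sub$n_union), summ(sub$n_intersection)
    )
    names(vals) <- as.vector(outer(
      c("mean", "min", "max"),
      c("nondegenerate", "lasso", "univariate", "union", "intersection"),
      function(a, b) paste(a, b, sep = "_")
    ))
    data.frame(keys[i, ], as.list(vals), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$predictability, -out$sample_size), ]
}
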