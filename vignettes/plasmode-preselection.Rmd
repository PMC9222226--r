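---
title: "Plasmode simulation of variable preselection for probability forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasmode simulation of variable preselection for probability forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

When a research team builds a clinical prediction model with a random
forest, should they restrict the candidate predictors to the variables that
*preceding studies* — typically analyzed with traditional regression tools —
found relevant? `plasmodeRF` implements a simulation framework for this
question in the setting typical of pharmacoepidemiologic registry data: a
large cohort, a binary outcome, and on the order of a thousand candidate
predictors, almost all of them sparse binary indicators (prescriptions,
diagnoses) whose prevalence spans several orders of magnitude.

The framework is *plasmode-style*: a fixed "population" data set supplies
the joint predictor structure, and the simulation repeatedly subsamples it.
Each replication draws four mutually disjoint samples without replacement:

* two **preceding studies**, analyzed once with cross-validated Lasso
  logistic regression and once with univariate significance screening
  followed by a multivariable logistic fit;
* a **current study**, which trains one probability random forest per
  preselection strategy;
* a **validation sample** on which every model is scored.

Because no suitable registry population can be redistributed, the package
ships a synthetic population generator with the registry's statistical
fingerprint; any user-supplied delimited-text population can be used
instead (`read_population()`).

## Models

**Preceding study 1 — Lasso.** The L1-penalized logistic log-likelihood is
maximized over a penalty path and the penalty is chosen by minimizing the
10-fold cross-validated binomial deviance (`glmnet::cv.glmnet`,
`lambda.min`). Variables with nonzero coefficients at the chosen penalty
form the selection. Predictors are left **unstandardized**: all binary
indicators share the 0/1 scale, and standardizing would inflate the weight
of the rarest columns. This choice changes which variables are selected and
is therefore surfaced here rather than buried in a default.

**Preceding study 2 — univariate selection.** Each candidate is tested with
a Wald test of the slope of a univariable logistic model; those with
p < 0.05 enter one multivariable logistic fit. The Wald flavor was chosen
over score or likelihood-ratio tests because it is the conventional default
and, for a binary predictor, available in closed form from the 2×2 table
(the MLE is the table log odds ratio, the SE the root of the summed
reciprocal cell counts), which makes screening ~1000 columns cheap. An
empty cell sends the Wald statistic to zero, so perfectly separated sparse
columns are — conservatively — never selected. When the multivariable fit
shows separation (common at n = 250 with sparse columns) a ridge-stabilized
fit (L2 penalty 10^-6^) replaces it, with a warning.

**Current study — probability forest.** `ranger::ranger(probability =
TRUE)`: unpruned trees on bootstrap resamples, Gini splitting, terminal-node
majority votes averaged over the ensemble. Defaults are the documented
ranger defaults — 500 trees, `mtry = floor(sqrt(p))`, minimum node size 10;
the 10%-of-n minimum-node-size variant is available by passing
`min_node_size` as a fraction. Within a replication all strategies share
one derived forest seed, so strategies whose candidate sets coincide
produce byte-identical forests.

**Strategies M1–M5.** M1 uses all non-degenerate current-study variables;
M2 the Lasso selection; M3 the intersection and M4 the union of the two
preceding selections; M5 the selection of whichever preceding model scores
the higher AUROC when applied *unchanged* (original coefficients) to the
current sample. Empty selections mean "no background knowledge": M2 and M4
fall back to all variables, M3 to M4's result, and M5 to the other model or
— if both are empty — to all variables. Variables degenerate in the current
sample are removed before resolution, so a set emptied by degeneracy falls
back the same way. Two tie-breaks the rules leave open are fixed here: an
AUROC tie in M5 goes to the Lasso model (the methodologically stronger
preceding study), and degenerate variables retained in a preceding model
are evaluated at their constant observed value when that model is applied
unchanged.

A sixth column, the **Lasso comparator**, is the same cross-validated Lasso
fitted on the current sample — a traditional-modeling reference point for
the forests.

## Performance measures

Validation predictions $\hat\pi_i$ with $\hat\eta_i =
\operatorname{logit}\hat\pi_i$ and outcomes $y_i$ are scored by:

* **AUROC**, with tied predictions counting ½ (ties are guaranteed when
  forests predict from sparse binary data);
* **Brier score** $\tfrac1N\sum_i (y_i - \hat\pi_i)^2$;
* **calibration slope**: the slope of the logistic regression (with
  intercept) of $y_i$ on $\hat\eta_i$; 1 is ideal, above 1 means underfit —
  predictions huddled too close to the event rate;
* **cross-entropy** $-\sum_i [y_i\log\hat\pi_i + (1-y_i)\log(1-\hat\pi_i)]$,
  reported as the **sum** over the validation set, together with its
  maximum single-observation contribution.

A single clipping constant, 10^-6^, is shared by every operation that takes
a logarithm or logit of a probability (cross-entropy, calibration slope,
reinforcement), keeping the measures finite and mutually consistent.
Replications whose calibration slope is non-finite or non-positive —
constant predictions, non-convergence — are excluded from the slope
summaries and counted in the output (`n_slope_excluded`); slopes across
replications are additionally summarized by the mean squared log slope,
whose ideal value is 0.

## The synthetic population

`generate_population()` emulates the registry fingerprint with:

* `p_binary` sparse binary columns (default 400) whose prevalences follow a
  piecewise log-linear quantile law anchored at the quartiles
  1/3371, 1/1530, 1/112 — the anchor quartiles of the motivating registry's
  prevalence distribution. A single log-uniform law cannot reproduce these
  three values because they are strongly asymmetric on the log scale; the
  piecewise law is the minimal extension that matches all three in
  expectation. Columns rarer than 1/n may be constant in the whole
  population: degenerate columns are part of the phenomenon under study,
  not an error.
* two standardized numeric columns (age and calendar-time analogues),
* a sparse additive logistic outcome model: the 5% most prevalent binary
  columns carry log-odds effects of ±0.34 (random signs) and the numeric
  columns 0.21 per SD, with the intercept solved numerically so the
  population event rate is 0.558. Placing the signal on the *common*
  columns reflects how registry outcomes are driven by common exposures and
  makes the preceding studies' task realistic — tens of selectable signal
  variables, not needles with three events apiece. The effect sizes were
  calibrated once so that a cross-validated probability forest reaches an
  AUROC of about 0.65 against the weak outcome, the regime the framework
  targets (weakly predictable outcome; the motivating registry analysis
  reported 0.646); with reinforcement (below) the strong-outcome AUROC
  lands near 0.83 and the strong event rate near 0.66.

What the generator deliberately does **not** emulate: correlations among
predictors (columns are independent; real substance indicators are likely
negatively correlated, and no correlation target is published to calibrate
against), ICD/ATC coding semantics, and any non-additive outcome structure.
Conclusions from passing tests therefore speak to the additive-signal,
independent-predictor regime; on real registry data the correlation
structure could shift, e.g., how much univariate selection overlaps the
Lasso.

## The reinforced outcome

To study a strongly predictable outcome without inventing a new data
generating mechanism, the weak outcome is *reinforced*
(`reinforce_population()`): the population is split into 4 random folds;
a probability forest trained on the other three folds predicts each fold
(so every row is predicted out-of-fold); predicted probabilities are mapped
to log odds, multiplied by 3.5, mapped back; and a new outcome is drawn
Bernoulli from the reinforced probabilities. The map `expit(c·logit(p))` is
strictly increasing with fixed point 0.5 and scales the logit variance by
c², so it strengthens the association while preserving the prediction
ranks. Forest outputs of exactly 0 or 1 are clipped at 10^-6^ before the
logit. Reinforcement is applied **once** and frozen on the population;
every scenario subsample reuses the same `y_strong`, making strong
predictability a property of the population rather than of a replication.

## Scenarios, seeding, outputs

A `scenario()` is a sample size (reference grid: 4000, 2000, 1000, 500,
250), a predictability arm, a replication count and a validation size. Each
replication's four samples are drawn disjointly without replacement —
overlap would leak information from "preceding" into "current" and into
validation. A draw producing a single-class sample is retried up to 5 times
with fresh derived seeds, then the replication aborts with a named error
(at event rate 0.56 this is practically unreachable).

Every stochastic component — row draws, CV folds, forests, Bernoulli
draws — takes its seed from `derive_seed(base_seed, scenario, replication,
component)`, so results are reproducible, independent of execution order,
and free of global RNG leakage; a rerun of `run_study()` with the same
inputs is byte-identical, including the files it writes (tidy
per-replication records, aggregate tables, a JSON manifest).

## Problem sizes and numerical choices

The package's default profile is desk-scale: a population of n = 10,000
with 402 predictors, validation samples of 2,000, and around 40–200
replications per scenario — chosen so a full directional experiment runs in
minutes on a laptop core while leaving every qualitative contrast
detectable. The reference study design (population ≈ 199,000, p = 1151,
validation 10,000, 1000 replications) is available by configuration; the
only cost is CPU time, which is dominated by the reinforcement step's four
population-scale forests.

Other numerical choices: quartiles use the type-7 (linear interpolation)
convention, pinned so the documented examples are exactly reproducible;
the intercept of the outcome model is solved with `uniroot` on [-30, 30] to
10^-10^; populations round-trip exactly through delimited text because
doubles are written with 17 significant digits.

## Known limitations

* Independent predictor columns (no correlation control is exposed).
* The scaled-down profile reproduces *directions* of the reference
  findings — under strong predictability the naive forest (M1) is the worst
  calibrated (mean slope above 1 and above M4's) while under weak
  predictability it attains the best cross-entropy — not absolute table
  values, which are properties of the restricted registry population.
* The Lasso comparator is fitted on the current study; evaluating the
  preceding study's Lasso on the validation set instead is a one-line
  variant (`predict_logistic` on the preceding `selection_result`).
* Permutation variable importance, elastic net and split-weight
  prioritization are out of scope.
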