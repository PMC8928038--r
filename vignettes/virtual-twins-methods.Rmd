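---
title: "Virtual twins for disparities in treatment access: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual twins for disparities in treatment access: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtdisparity)
```

## The problem

Episode-level treatment registries record, for every admission, a binary
adverse access outcome (here: waiting one day or more to enter
opioid-use-disorder treatment rather than entering the same day), a binary
group attribute (race recorded as African American vs White), and a few
dozen categorical or ordinal covariates (state, age band, referral source,
service setting, medication-assisted therapy, housing status, ...). Marginal
comparisons of the two groups can be misleading in both directions: a
group can appear advantaged overall while being substantially disadvantaged
inside specific covariate-defined subpopulations (a Simpson-style
reversal). The question this package answers is *where* the group attribute
most increases the probability of the adverse outcome, phrased as an
explicit, auditable conjunction of covariate conditions.

## The two-step virtual-twins procedure

Write $Y_i \in \{0,1\}$ for the outcome, $D_i \in \{0,1\}$ for the group
attribute and $X_i$ for the covariates. The procedure implemented by
`virtual_twins()` is:

1. Split the analytic table once into a training part (20% by default) and
   an estimation part (80%).
2. On the training part, fit a probability classifier
   $f(D, X) \approx P(Y = 1 \mid D, X)$ with the group attribute among the
   predictors (`fit_wait_model()`).
3. On the estimation part, score every episode **twice**, once under each
   value of the group attribute, and form the *virtual probability
   difference* $$Z_i = f(1, X_i) - f(0, X_i),$$ the extra probability of
   the adverse outcome attributable solely to group membership at covariates
   $X_i$ — regardless of the episode's actual group
   (`compute_virtual_differences()`).
4. Grow a CART-style regression tree on $(X, Z)$ over the estimation rows,
   with the group attribute structurally excluded from the covariates
   (`fit_regression_tree()`; the exclusion is enforced, not conventional).
5. Read one subgroup rule off each root-to-leaf path
   (`extract_subgroup_rules()`) and select the leaf with maximal mean $Z$
   among leaves with adequate coverage (`select_most_vulnerable()`).

A single split is used for the final interpretable run: averaging trees
over many splits would defeat the point of an auditable rule. Repeated
random splits live in the classifier-comparison harness
(`compare_classifiers()`), which reports misclassification (overall and per
group, threshold 0.5) and rank-statistic AUC over replicates.

The selected rule — and every other leaf rule — is then re-applied to the
*full* table by `validate_subgroups()`: inside each subgroup the two
groups' outcome proportions are compared with a pooled two-proportion test
with continuity correction, against a Bonferroni threshold of
$\alpha / L$ with $L$ the number of (evaluable) tree leaves. The marginal
comparison on the whole table is reported alongside, and a reversal flag
records when the selected subgroup's disparity and the marginal disparity
have opposite signs.

### Why the continuity correction is the default

With the correction, the test statistic is
$z = \max(0, |p_1 - p_2| - \tfrac12(1/n_1 + 1/n_2)) /
\sqrt{\hat p(1-\hat p)(1/n_1+1/n_2)}$ and $z^2$ equals the Yates-corrected
$2\times2$ chi-square. On the published California subgroup table
(117/426 vs 920/5084) the corrected test reproduces the reported
$p = 2.77\times10^{-6}$ exactly, while the uncorrected test gives
$2.0\times10^{-6}$; the corrected variant is therefore the default, with
`correct = FALSE` available.

## Step-1 classifiers

Three families are built in, each behind the same one-hot design with
category dictionaries frozen at preparation time, so training, test and
counterfactual scoring can never disagree about the schema:

* `random_forest` — **per-group probability forests** (one ranger forest
  per value of $D$). This is the package default, and the choice deserves
  its own paragraph (below).
* `elastic_net` — glmnet logistic regression, $\alpha = 0.5$, lambda by
  5-fold cross-validation.
* `boosting_tree` — xgboost, 200 rounds, learning rate 0.1, depth 4.

Hyperparameters are not sacred: they are plain `params` entries, logged in
run reports. Defaults are each family's conventional settings.

### Why per-group forests

$Z$ is a *difference* of probabilities at the same covariates, so Step 1
must capture how the group effect varies with covariates — a
group-by-covariate interaction. A single pooled forest over $(D, X)$
estimates such interactions only through consecutive splits on $D$ and the
interacting covariates; at moderate training sizes and minority-group
shares around 16%, the forest's smoothing shrinks exactly this structure,
and the fitted $Z$ surface degenerates into noise around the group main
effect. In controlled experiments with a planted subgroup (below), the
pooled forest's fitted inside-vs-outside $Z$ gap was about a sixth of the
true gap — too little to steer the Step-2 tree. Fitting one forest per
group removes the need to discover splits on $D$ altogether: each forest
estimates its own group's outcome surface, and the difference inherits
whatever either surface supports. Both alternatives remain available
(`params$per_group = FALSE`, optionally with explicit $D \times X$
interaction features via `params$interactions = TRUE`).

The per-group forests consume the covariates as factors and allow
set-valued ("partition") categorical splits, so a condition like
"state in {CA, MD}" is reachable in one split rather than a chain of
one-level splits.

## The Step-2 regression tree

The tree is plain CART for regression: greedy recursive partitioning
maximizing the SSE reduction
$\Delta = SSE(\text{parent}) - SSE(\text{left}) - SSE(\text{right})$, with
leaf predictions equal to the leaf mean of $Z$. Categorical split search
orders levels by mean response and scans contiguous cut points, which
attains the exhaustive-bipartition optimum for squared-error loss (verified
against brute force in the test suite up to 8 levels); ordinal variables
split by threshold on their level order. The left branch always holds the
rows *satisfying* the condition, the display convention of subgroup-tree
figures in this literature.

Stopping rules, all configurable through `tree_params()`:

* `max_depth = 4` — subgroup rules beyond four conditions stop being
  interpretable;
* `min_leaf` — 1% of the fitting rows by default, so no reported subgroup
  is vanishingly small; `min_split = 2 * min_leaf`;
* `min_gain = 0` (absolute) together with `cp = 0.01` (relative): a split
  must reduce SSE by at least 1% of the root-node SSE. The relative
  threshold is the CART/rpart growth convention; without it, any positive
  gain — and with estimated $Z$ there always is one — would grow every
  branch to full depth, producing 16-leaf trees of mostly noise splits.
  With it, trees on realistic inputs come out at 3–12 leaves, the size at
  which path conjunctions remain readable. No pruning pass is applied.

Exact ties between candidate splits prefer the variable earlier in column
order, then the smaller satisfying level subset; splitting is otherwise
fully deterministic, and the weighted leaf-mean identity
$\sum_\ell (n_\ell/n)\,\bar z_\ell = \bar z$ is asserted to $10^{-12}$ in
the tests.

## The synthetic episode generator

Restricted-access registry microdata cannot ship with a package, so all
development and testing runs on synthetic episode tables from a fully
specified logistic model:
$$\operatorname{logit} P(Y=1 \mid D, X) = \beta_0 + \textstyle\sum_j
\beta_j(X_j) + (\delta_0 + \delta_S\,1[X \in S])\,D,$$
with independently sampled covariates, $D \sim$
Bernoulli(`race_prevalence`), and a planted subgroup $S$ defined as a
conjunction of level conditions. Because the group attribute enters only
through $\delta_0$ and $\delta_S$, the planted conjunction is the unique
region of elevated counterfactual difference, and
`true_virtual_difference()` returns the exact oracle
$Z(X) = \operatorname{expit}(\eta + \delta_0 + \delta_S 1[X\in S]) -
\operatorname{expit}(\eta)$ for any covariate vector.

Two reference configurations ship with the package:

* `default_generator_config()` — the *realism-oriented* conditions: ten
  covariates led by an 8-level state indicator, focal-group prevalence
  0.16 (the share of African American episodes in the national analytic
  sample the motivating analysis reports), modest covariate effects, and a
  planted subgroup (state in {CA, MD} and medication-assisted treatment)
  holding about 13% of episodes. $\delta_0 = -0.3$ and $\delta_S = 0.6$
  give a true inside-subgroup $Z$ near $+0.065$ against $-0.06$ outside,
  so the marginal association *favors* the focal group while the subgroup
  association reverses it — the Simpson-style pattern of the motivating
  study. The intercept $-1.30619$ was set with `calibrate_intercept()` so
  the marginal outcome prevalence is 0.302, matching the national wait
  prevalence (284,235 of 941,286 episodes).
* `recovery_generator_config()` — the *controlled recovery* conditions
  used to measure whether the pipeline rediscovers a known planted rule:
  the same schema with the covariate main effects removed, intercept
  $-2.5$, $\delta_0 = -0.3$ and $\delta_S = 0.9499$ solved in closed form
  so the true inside-subgroup $Z$ is exactly $0.060$ while outside it is a
  flat $-0.019$ — a step surface, nothing for the Step-2 tree to find
  except the planted conjunction (plus estimation noise). The focal-group
  share is 0.34, the share observed in the validated Maryland subgroup of
  the motivating analysis (its national sample share, 0.16, is kept in the
  default configuration): recovering a group-by-covariate interaction is
  information-limited by the count of focal-group outcome events inside
  the planted cell, and at much lower shares the Step-1 training part of a
  50,000-episode study simply does not contain enough of them for any
  classifier to resolve the cell. With the exact oracle $Z$ in place of
  Step 1, the default tree recovers the planted pair in every tested seed
  with clean 3-leaf trees, so any recovery failure under the full pipeline
  is attributable to Step-1 estimation.

What the generator deliberately does **not** emulate: covariate
correlation (registry covariates are far from independent), person-level
episode clustering, state-specific sample-size imbalance, and informative
missingness (`inject_missing_and_unknowns()` corrupts cells completely at
random; "Unknown" responses are a regular category, missing cells are
deleted row-wise by `prepare_analytic_table()`, each row counted in exactly
one drop bucket: unknown wait first, then non-retained race, then missing
cells). Passing recovery tests on this generator therefore demonstrates
that the pipeline's machinery is sound, not that any particular real-data
finding is correct.

## Problem sizes and numerical choices

The shipped experiments use $n = 50{,}000$ episodes with a 20/80 split
(10,000 training rows), the scale at which a laptop run stays comfortable;
the motivating analyses used state samples about four times larger.
Monte-Carlo checks of generator calibration use $n = 100{,}000$.
Probabilities returned by classifiers are clamped to $[0,1]$ only against
floating-point spill (tolerance $10^{-12}$); degenerate proportion tests
(pooled proportion 0 or 1) return $p = 1$ with a warning rather than NaN;
p-values below `2.2e-16` are additionally reported as the label
`"< 2.20e-16"`, the conventional double-precision floor. All randomness
derives from explicit seeds; pipeline stages derive their own seeds from
the master seed by hashing the stage name, so editing one stage's
configuration never perturbs another stage's stream.

## Known limitations

* The virtual differences are point predictions; no uncertainty
  accompanies individual $Z_i$, and the Step-2 tree treats them as data.
  The full-data proportion tests are the procedure's inferential guardrail.
* Bonferroni over tree leaves controls multiplicity over the *reported*
  comparisons, not over the tree-search space; subgroup estimates remain
  subject to selection optimism (the validation on raw counts, rather than
  on $Z$, limits but does not remove this).
* Full-data validation — re-applying the rules to *all* episodes, the
  convention of the motivating analysis — is not fully independent of the
  discovery step: the training fraction of the validated episodes is the
  very data whose outcome noise Step 1 fitted and the tree then selected
  on. Under a race-blind null this leaks detectable anticonservatism into
  the leaf tests (the test suite quantifies it), and it disappears when
  validation is restricted to the held-out estimation part — at the price
  of the training fraction of the sample. Callers who want leakage-free
  tests should pass `table[fit$estimation_idx, ]` to
  `validate_subgroups()`; the pipeline default keeps the full-data
  convention for comparability.
* With estimated rather than oracle $Z$, the most-vulnerable leaf usually
  carries one extra noise condition beyond the planted or true rule: the
  tree refines the genuine subgroup on the classifier's error surface
  before the growth threshold stops it. Reported rules should be read as
  "at most this specific": their variable supersets and region are
  reliable well before their exact boundaries are.
* With minority-group shares well below the 16% studied here, per-group
  forests will starve; the elastic net with interactions or boosting are
  then the more stable Step-1 choices.
* Covariates are treated as exchangeable categorical codes; no notion of
  distance between state codes or adjacent age bands beyond ordinal order
  is used.
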