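# vtdisparity

Two-step **virtual twins** subgroup analysis for health-disparities
questions: find the covariate-defined subgroup of treatment episodes in
which a binary group attribute (here, race recorded as African American vs
White) most increases the probability of a binary adverse access outcome
(waiting one day or more to enter opioid-use-disorder treatment), then
validate the finding with corrected proportion tests on the full data.

It is written for biostatisticians and health-services researchers working
with episode-level admission registries, where marginal group comparisons
can point in the *opposite* direction from the conditional comparisons that
matter (a Simpson-style reversal).

## Method

For episodes $(Y_i, D_i, X_i)$ with binary outcome $Y$, group $D$ and
covariates $X$:

1. **Step 1** — split the data 20/80 once; on the 20% fit a probability
   classifier $f(D, X) \approx P(Y = 1 \mid D, X)$ (per-group random
   forests by default; elastic net and gradient boosting built in).
2. **Virtual difference** — on the 80%, score every episode under both
   group values: $Z_i = f(1, X_i) - f(0, X_i)$, the extra probability of
   the adverse outcome attributable solely to group membership.
3. **Step 2** — grow a CART regression tree on $(X, Z)$ with the group
   attribute structurally excluded; each root-to-leaf path is a candidate
   subgroup rule; the leaf with maximal mean $Z$ is the *most vulnerable
   subgroup*.
4. **Validation** — apply every rule to the full table and compare the two
   groups' outcome proportions with a pooled two-proportion test with
   continuity correction ($z^2$ = Yates chi-square) at the Bonferroni
   threshold $\alpha / L$, $L$ = number of tree leaves, alongside the
   marginal comparison and a reversal flag.

A synthetic episode generator with a fully specified logistic outcome model
and a planted subgroup (plus a closed-form oracle for the true $Z$) stands
in for restricted-access registry microdata throughout.

## Worked example

```r
library(vtdisparity)

# the published California subgroup contingency table:
# 117/426 African American vs 920/5084 White episodes waiting >= 1 day
two_proportion_test(117, 426, 920, 5084)
#> p1 = 0.2746, p2 = 0.1810, X-squared = 21.97, p = 2.766e-06
bonferroni_threshold(0.05, 8)
#> [1] 0.00625   # significant even after correcting for the 8 leaves

# end-to-end on synthetic data with a planted vulnerable subgroup
# (state in {CA, MD} and medication-assisted treatment)
cfg <- default_generator_config(n_episodes = 50000)
tab <- generate_episodes(cfg, seed = 1)
fit <- virtual_twins(tab, seed = 1)
print(fit)
#> Virtual-twins subgroup analysis
#>   Step 1: random_forest on 10000 episodes (train fraction 0.20)
#>   Step 2: regression tree on Z over 40000 episodes, 13 leaves
#>   Z: mean -0.0205, range [-0.2841, +0.3555]
#>   Most vulnerable subgroup:
#>      state in {CA} AND mat not in {No} AND route in {Smoking}
#>        ->  mean Z = +0.1540, n = 591 (1%)

validate_subgroups(fit, tab)   # per-leaf tests + marginal row + reversal flag
plot(fit)                      # the regression tree, leaf = mean Z and coverage
```

The selected rule lies inside the planted subgroup (with one extra noise
refinement, typical at this training size — see the methods vignette). The
validation table confirms the Simpson-style pattern the generator plants:
inside the selected subgroup African American episodes wait more
(66/129 = 51.2% vs 202/622 = 32.5%, p = 8.5e-05), while marginally they
appear to wait *less* (27.1% vs 30.6%), and the reversal flag is raised.

`run_pipeline()` (or the thin CLI in `inst/scripts/vt-pipeline.R`) chains
simulate → prepare → compare-models → virtual twins → validate into a
reproducible run directory with every seed logged.

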