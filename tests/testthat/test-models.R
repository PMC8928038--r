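# fast classifier settings used throughout the model tests
fast_rf <- function(seed = 1L)
  classifier_spec("random_forest", list(num_trees = 100), seed = seed)
fast_boost <- function(seed = 1L)
  classifier_spec("boosting_tree", list(nrounds = 40), seed = seed)

sim_table <- function(n, seed, beta = list(a = c(a2 = 1.5)),
                      planted = planted_subgroup()) {
  cfg <- tiny_config(n = n, intercept = -0.5, beta = beta, planted = planted,
                     race_prevalence = 0.4, seed = seed)
  generate_episodes(cfg)
}

test_that("fitting is deterministic per spec seed and refuses single-class outcomes", {
  tab <- sim_table(600, seed = 1)
  probe <- sim_table(100, seed = 2)
  for (spec in list(fast_rf(), classifier_spec("elastic_net"), fast_boost())) {
    m1 <- fit_wait_model(tab, spec)
    m2 <- fit_wait_model(tab, spec)
    expect_equal(predict_wait_probability(m1, NULL, probe),
                 predict_wait_probability(m2, NULL, probe),
                 tolerance = 1e-12, info = spec$method)
  }
  bad <- tab
  bad$wait_binary <- 0L
  expect_error(fit_wait_model(bad, fast_rf()), class = "vt_fit_error")
})

test_that("predictions are probabilities and counterfactual scoring works under both group values", {
  tab <- sim_table(800, seed = 3,
                   planted = planted_subgroup(list(a = "a1"), 0.5, 0.8))
  probe <- sim_table(500, seed = 4)
  m <- fit_wait_model(tab, fast_rf())
  p1 <- predict_wait_probability(m, 1, probe)
  p0 <- predict_wait_probability(m, 0, probe)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_true(all(p0 >= 0 & p0 <= 1))
  expect_error(predict_wait_probability(m, 2, probe),
               class = "vt_config_error")
  # unseen level is refused by name
  probe2 <- probe
  levels(probe2$a) <- c("a1", "zz")
  expect_error(predict_wait_probability(m, 1, probe2),
               class = "vt_schema_error")
})

test_that("a lookup-table stub model reproduces its table exactly", {
  spec <- register_lookup_stub(p1 = 0.6, p0 = 0.4)
  tab <- sim_table(50, seed = 5)
  m <- fit_wait_model(tab, spec)
  expect_equal(predict_wait_probability(m, 1, tab), rep(0.6, 50))
  expect_equal(predict_wait_probability(m, 0, tab), rep(0.4, 50))
})

test_that("a model with no access to race gives identical output under both group values", {
  spec <- register_raceblind_stub()
  tab <- sim_table(120, seed = 6)
  m <- fit_wait_model(tab, spec)
  expect_equal(predict_wait_probability(m, 1, tab),
               predict_wait_probability(m, 0, tab))
})

test_that("rank-statistic AUC equals hand-counted concordant-pair fractions", {
  # scores .9 .8 .4 .2 .7 .1 for labels 1 1 0 1 0 0:
  # pairs (1-label, 0-label): 9 total, concordant: count by enumeration
  scores <- c(0.9, 0.8, 0.4, 0.2, 0.7, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  hand <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(vtdisparity:::rank_auc(scores, labels), hand)
  # ties handled as half-concordant
  expect_equal(vtdisparity:::rank_auc(c(0.5, 0.5), c(1, 0)), 0.5)
})

test_that("AUC is invariant to strictly monotone transforms of the scores", {
  set.seed(8)
  for (i in 1:20) {
    sc <- runif(60)
    lb <- rbinom(60, 1, 0.4)
    if (length(unique(lb)) < 2) next
    a0 <- vtdisparity:::rank_auc(sc, lb)
    expect_equal(vtdisparity:::rank_auc(qlogis(sc / 1.0001 + 1e-6), lb), a0)
    expect_equal(vtdisparity:::rank_auc(sc^3 + 2, lb), a0)
  }
})

test_that("comparison harness: constant-score stub gives ~50% misclassification and AUC 0.5", {
  register_classifier("constant_stub",
    fit = function(x, y, params, seed) NULL,
    predict = function(fit, x) rep(0.5, nrow(x)))
  tab <- generate_episodes(tiny_config(n = 400, intercept = 0, seed = 9))
  rep <- compare_classifiers(tab, list(classifier_spec("constant_stub")),
                             n_reps = 3, train_frac = 0.5, seed = 1)
  expect_equal(rep$summary$auc_mean, 0.5)
  # constant 0.5 is never > 0.5, so everything is classified 0:
  # misclassification equals the outcome prevalence of the test part (~50%)
  expect_lt(abs(rep$summary$mis_overall_mean - 50), 6)
})

test_that("perfectly separable data reach zero test misclassification and AUC 1 for all three families", {
  set.seed(10)
  n <- 400
  tab <- data.frame(
    a = factor(sample(c("a1", "a2"), n, replace = TRUE)),
    b = factor(sample(c("b1", "b2"), n, replace = TRUE)),
    race = factor(sample(c("White", "African American"), n, replace = TRUE),
                  levels = c("White", "African American")))
  tab$wait_binary <- as.integer(tab$a == "a2")
  rep <- compare_classifiers(
    tab, list(fast_rf(), classifier_spec("elastic_net"), fast_boost()),
    n_reps = 2, train_frac = 0.5, seed = 2)
  expect_equal(rep$summary$mis_overall_mean, rep(0, 3))
  expect_equal(rep$summary$auc_mean, rep(1, 3))
})

test_that("misclassification identities hold on every replicate", {
  tab <- sim_table(500, seed = 11)
  rep <- compare_classifiers(tab, fast_boost(), n_reps = 4,
                             train_frac = 0.3, seed = 3)
  r <- attr(rep, "replicates")
  # group-wise misclassification averages (weighted) to the overall value
  w1 <- r$n_group1 / r$n_test
  expect_equal(r$mis_overall, w1 * r$mis_group1 + (1 - w1) * r$mis_group0,
               tolerance = 1e-9)
  expect_true(all(r$mis_overall >= 0 & r$mis_overall <= 100))
  expect_true(all(r$auc >= 0 & r$auc <= 1))
})

test_that("an outcome independent of all predictors yields near-chance test AUC", {
  set.seed(12)
  n <- 5000
  tab <- data.frame(
    wait_binary = rbinom(n, 1, 0.4),
    race = factor(sample(c("White", "African American"), n, replace = TRUE),
                  levels = c("White", "African American")),
    a = factor(sample(c("a1", "a2"), n, replace = TRUE)),
    b = factor(sample(letters[1:4], n, replace = TRUE)))
  rep <- compare_classifiers(tab, fast_boost(), n_reps = 2,
                             train_frac = 0.2, seed = 4)
  expect_gt(rep$summary$auc_mean, 0.45)
  expect_lt(rep$summary$auc_mean, 0.55)
})

test_that("model fitted on a known logistic model approaches the generating model's own AUC", {
  cfg <- tiny_config(n = 6000, intercept = -0.5,
                     beta = list(a = c(a2 = 1.2), b = c(b2 = -0.8)),
                     race_prevalence = 0.4, seed = 13)
  tab <- generate_episodes(cfg)
  parts <- split_once(tab, 0.5, seed = 14)
  m <- fit_wait_model(parts$train, fast_boost())
  p_hat <- predict_wait_probability(m, NULL, parts$estimation)
  # Bayes scorer: the true conditional probability from the generator
  covs <- parts$estimation[c("a", "b")]
  eta <- -0.5 + 1.2 * (covs$a == "a2") - 0.8 * (covs$b == "b2")
  p_true <- plogis(eta)
  y <- parts$estimation$wait_binary
  auc_hat <- vtdisparity:::rank_auc(p_hat, y)
  auc_bayes <- vtdisparity:::rank_auc(p_true, y)
  expect_lt(abs(auc_hat - auc_bayes), 0.03)
})

test_that("fitted models round-trip through their serialization artifact", {
  tab <- sim_table(400, seed = 21)
  m <- fit_wait_model(tab, fast_boost())
  f <- tempfile(fileext = ".rds")
  save_wait_model(m, f)
  m2 <- load_wait_model(f)
  expect_equal(m2$fingerprint, m$fingerprint)
  expect_equal(predict_wait_probability(m2, 1, tab),
               predict_wait_probability(m, 1, tab))
  saveRDS(list(format = "other"), f)
  expect_error(load_wait_model(f), class = "vt_config_error")
})

test_that("variable importance ranks a planted single signal first and covers all predictors", {
  hits <- 0
  for (seed in 1:10) {
    tab <- sim_table(2000, seed = 100 + seed, beta = list(a = c(a2 = 1.5)))
    m <- fit_wait_model(tab, fast_rf(seed = seed))
    imp <- variable_importance(m)
    expect_setequal(imp$variable, c("race", "a", "b"))
    expect_true(all(imp$importance >= 0))
    if (imp$variable[1] == "a") hits <- hits + 1
    # pure-noise covariate never beats the signal covariate
    expect_lte(imp$importance[imp$variable == "b"],
               imp$importance[imp$variable == "a"])
  }
  expect_gte(hits, 9)
  register_classifier("no_imp_stub",
    fit = function(x, y, params, seed) NULL,
    predict = function(fit, x) rep(0.5, nrow(x)))
  m2 <- fit_wait_model(sim_table(50, seed = 15),
                       classifier_spec("no_imp_stub"))
  expect_error(variable_importance(m2), class = "vt_capability_error")
})
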