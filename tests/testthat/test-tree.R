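test_that("tree_params validates its invariants", {
  expect_error(tree_params(max_depth = 0), class = "vt_config_error")
  expect_error(tree_params(min_leaf = 0), class = "vt_config_error")
  expect_error(tree_params(min_split = 3, min_leaf = 2),
               class = "vt_config_error")
  expect_error(tree_params(min_gain = -1), class = "vt_config_error")
})

test_that("constant z admits no split and non-finite z errors", {
  x <- factor(rep(c("a", "b"), 20))
  expect_null(best_split(x, rep(0.3, 40), tree_params(min_leaf = 1)))
  expect_error(best_split(x, c(rep(1, 39), NaN), tree_params()),
               class = "vt_data_error")
})

test_that("binary covariate split gain matches hand SSE arithmetic", {
  # z = 0.2 on level A (10 rows), 0.0 on level B (10 rows):
  # parent SSE = 20 * Var = 0.2, children are pure, gain = 0.2
  x <- factor(rep(c("A", "B"), each = 10))
  z <- rep(c(0.2, 0), each = 10)
  sp <- best_split(x, z, tree_params(min_leaf = 1), variable = "g")
  expect_equal(sp$gain, 0.2, tolerance = 1e-12)
  expect_equal(sp$condition$levels, "A")
  expect_equal(sp$condition$variable, "g")
})

test_that("mean-ordering categorical search attains the exhaustive-bipartition optimum", {
  # 6-level categorical: 2^5 - 1 = 31 bipartitions, 50 random instances
  for (seed in 1:50) {
    set.seed(seed)
    n <- 200
    x <- factor(sample(letters[1:6], n, replace = TRUE))
    z <- rnorm(n) + 0.5 * (x %in% c("b", "e"))
    sp <- best_split(x, z, tree_params(min_leaf = 1))
    oracle <- exhaustive_best_split(data.frame(x = x), z, min_leaf = 1)
    expect_equal(sp$gain, oracle$gain, tolerance = 1e-9)
  }
  # and up to 8 levels
  for (seed in 1:20) {
    set.seed(100 + seed)
    n <- 300
    x <- factor(sample(letters[1:8], n, replace = TRUE))
    z <- rnorm(n, mean = as.integer(x) %% 3)
    sp <- best_split(x, z, tree_params(min_leaf = 1))
    oracle <- exhaustive_best_split(data.frame(x = x), z, min_leaf = 1)
    expect_equal(sp$gain, oracle$gain, tolerance = 1e-9)
  }
})

test_that("ordinal splits scan thresholds in level order and respect min_leaf", {
  x <- factor(c(rep("lo", 5), rep("mid", 5), rep("hi", 5)),
              levels = c("lo", "mid", "hi"), ordered = TRUE)
  z <- c(rep(0, 10), rep(1, 5))
  sp <- best_split(x, z, tree_params(min_leaf = 1))
  expect_equal(sp$condition$kind, "ordinal")
  expect_equal(sp$condition$threshold, 2) # <= mid
  expect_equal(sp$condition$threshold_label, "mid")
  # min_leaf = 6 forbids the pure cut; the admissible alternative is <= lo
  x2 <- factor(c(rep("lo", 6), rep("mid", 6), rep("hi", 3)),
               levels = c("lo", "mid", "hi"), ordered = TRUE)
  z2 <- c(rep(0, 12), rep(1, 3))
  sp6 <- best_split(x2, z2, tree_params(min_leaf = 6))
  expect_equal(sp6$condition$threshold, 1)
  # and no admissible cut at all returns NULL
  expect_null(best_split(x, z, tree_params(min_leaf = 6)))
})

test_that("depth-1 trees equal global brute-force best single split on random instances", {
  for (seed in 1:50) {
    inst <- random_tree_instance(n = 120, seed = seed)
    tree <- fit_regression_tree(
      inst$X, inst$z,
      tree_params(max_depth = 1, min_leaf = 1, min_split = 2, cp = 0))
    oracle <- exhaustive_best_split(inst$X, inst$z, min_leaf = 1)
    root <- tree$nodes[["1"]]
    if (is.null(oracle) || oracle$gain <= 0) {
      expect_null(root$split)
    } else {
      expect_equal(root$gain, oracle$gain, tolerance = 1e-9)
    }
  }
})

test_that("single-signal z yields a depth-1 tree splitting exactly that covariate", {
  set.seed(2)
  n <- 400
  X <- data.frame(
    sig = factor(sample(c("yes", "no"), n, replace = TRUE)),
    noise = factor(sample(letters[1:4], n, replace = TRUE)))
  z <- ifelse(X$sig == "yes", 0.3, -0.1)
  tree <- fit_regression_tree(X, z, tree_params())
  rules <- extract_subgroup_rules(tree)
  expect_equal(length(rules), 2)
  expect_equal(tree$nodes[["1"]]$split$variable, "sig")
})

test_that("degenerate fits return a single mean-predicting leaf", {
  X <- data.frame(a = factor(rep(c("x", "y"), 10)))
  tree <- fit_regression_tree(X, rep(0.25, 20), tree_params(max_depth = 1))
  expect_equal(length(tree_leaves <- extract_subgroup_rules(tree)), 1)
  expect_equal(tree_leaves[[1]]$mean_z, 0.25)
  expect_equal(tree_leaves[[1]]$coverage, 1)
})

test_that("leaf means conserve the overall mean and coverages sum to 1 on every fit", {
  for (seed in 1:20) {
    inst <- random_tree_instance(n = 300, n_levels = 5, seed = 400 + seed)
    tree <- fit_regression_tree(inst$X, inst$z,
                                tree_params(max_depth = 4, cp = 0))
    rules <- extract_subgroup_rules(tree)
    means <- vapply(rules, function(r) r$mean_z, numeric(1))
    ns <- vapply(rules, function(r) r$n, numeric(1))
    covs <- vapply(rules, function(r) r$coverage, numeric(1))
    expect_equal(sum(means * ns) / sum(ns), mean(inst$z), tolerance = 1e-12)
    expect_equal(sum(covs), 1, tolerance = 1e-12)
    expect_equal(sum(ns), length(inst$z))
  }
})

test_that("accepted splits never increase SSE and total SSE is monotone in max_depth", {
  inst <- random_tree_instance(n = 500, n_levels = 6, seed = 77)
  tree_sse <- function(depth) {
    tree <- fit_regression_tree(inst$X, inst$z,
                                tree_params(max_depth = depth, cp = 0))
    sum(vapply(Filter(function(nd) is.null(nd$split), tree$nodes),
               function(nd) nd$sse, numeric(1)))
  }
  sses <- vapply(1:4, tree_sse, numeric(1))
  expect_true(all(diff(sses) <= 1e-9))
  expect_true(all(sses <= vtdisparity:::node_sse(inst$z) + 1e-9))
})

test_that("a group column among the tree covariates is a contract violation", {
  X <- data.frame(race = factor(rep(c("W", "AA"), 10)),
                  a = factor(rep(c("x", "y"), each = 10)))
  expect_error(fit_regression_tree(X, rnorm(20), tree_params()),
               class = "vt_contract_error")
})

test_that("extracted rules partition the estimation rows exactly", {
  inst <- random_tree_instance(n = 400, n_levels = 6, seed = 11)
  tree <- fit_regression_tree(inst$X, inst$z, tree_params(cp = 0))
  rules <- extract_subgroup_rules(tree)
  hits <- vapply(rules, function(r)
    vtdisparity:::rule_mask(r, inst$X), logical(nrow(inst$X)))
  expect_true(all(rowSums(hits) == 1)) # exactly one rule per row
  for (i in seq_along(rules)) # rule reproduces its leaf's row count
    expect_equal(sum(hits[, i]), rules[[i]]$n)
  # routing agrees with rule masks
  ids <- route_to_leaves(tree, inst$X)
  for (i in seq_along(rules))
    expect_equal(sum(ids == rules[[i]]$leaf_id), rules[[i]]$n)
})

test_that("most-vulnerable selection maximizes mean Z with documented tie-breaks", {
  mk <- function(mean_z, coverage, id) structure(
    list(conditions = list(), mean_z = mean_z, n = round(100 * coverage),
         coverage = coverage, leaf_id = id), class = "subgroup_rule")
  rules <- structure(list(mk(0.01, 0.3, 2L), mk(0.059, 0.2, 6L),
                          mk(-0.067, 0.5, 7L)), class = "subgroup_rules")
  expect_equal(select_most_vulnerable(rules)$mean_z, 0.059)
  ties <- structure(list(mk(0.05, 0.03, 2L), mk(0.05, 0.12, 3L)),
                    class = "subgroup_rules")
  expect_equal(select_most_vulnerable(ties)$coverage, 0.12)
  single <- structure(list(mk(0.02, 1, 1L)), class = "subgroup_rules")
  expect_equal(select_most_vulnerable(single)$leaf_id, 1L)
  expect_error(select_most_vulnerable(rules, min_coverage = 0.9),
               class = "vt_selection_error")
})

test_that("renderings label leaves with mean and coverage and DOT output is well-formed", {
  X <- data.frame(a = factor(rep(c("x", "y"), each = 30)),
                  b = factor(rep(c("u", "v"), 30)))
  z <- 0.1 * (X$a == "x") + 0.05 * (X$b == "u") + rnorm(60, sd = 0.01)
  tree <- fit_regression_tree(X, z, tree_params(min_leaf = 5, cp = 0,
                                                max_depth = 2))
  single <- fit_regression_tree(X, rep(0.1234, 60), tree_params())
  txt1 <- render_tree(single, "text")
  expect_match(txt1, "0.1234")
  expect_match(txt1, "100%")
  # coverage labels sum to ~100
  txt <- render_tree(tree, "text")
  pcts <- as.numeric(gsub(".*\\((\\d+)%.*", "\\1",
                          grep("leaf", strsplit(txt, "\n")[[1]],
                               value = TRUE)))
  expect_lte(abs(sum(pcts) - 100), length(pcts) / 2)
  dot <- render_tree(tree, "dot")
  expect_match(dot, "^digraph")
  # structural well-formedness: balanced braces, edges reference declared
  # nodes, one label per node line
  expect_equal(lengths(regmatches(dot, gregexpr("\\{", dot))),
               lengths(regmatches(dot, gregexpr("\\}", dot))))
  lines <- strsplit(dot, "\n")[[1]]
  decl <- gsub("^\\s*(n\\d+) \\[.*", "\\1",
               grep("^\\s*n\\d+ \\[", lines, value = TRUE))
  edges <- regmatches(dot, gregexpr("n\\d+ -> n\\d+", dot))[[1]]
  for (e in edges) {
    ends <- strsplit(e, " -> ")[[1]]
    expect_true(all(ends %in% decl))
  }
  expect_error(render_tree(tree, "svg"))
})
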