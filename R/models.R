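# Step-1 probability classifiers P(Y = 1 | D, X) behind a common contract:
# one-hot design with a frozen category dictionary, so training, testing and
# counterfactual scoring all share the same schema.

.classifier_registry <- new.env(parent = emptyenv())

#' Register a classifier family
#'
#' Extends the classifier registry beyond the three built-in families. Used
#' mainly to plug stub models into the pipeline for testing.
#'
#' @param method family name.
#' @param fit `function(x, y, params, seed)` returning an opaque fitted
#'   state; `x` is the numeric one-hot design matrix (first column `D`),
#'   `y` the integer 0/1 outcome.
#' @param predict `function(fit, x)` returning probabilities in `[0, 1]`.
#' @param importance optional `function(fit, x_colnames)` returning a named
#'   non-negative score per design column, or `NULL` if unsupported.
#' @export
register_classifier <- function(method, fit, predict, importance = NULL) {
  assign(method, list(fit = fit, predict = predict, importance = importance),
         envir = .classifier_registry)
  invisible(method)
}

classifier_entry <- function(method) {
  if (!exists(method, envir = .classifier_registry))
    vt_stop(sprintf("unknown classifier family '%s'", method),
            "vt_config_error")
  get(method, envir = .classifier_registry)
}

#' Specify a Step-1 classifier
#'
#' Built-in families: `random_forest` (per-group ranger probability
#' forests — one forest per value of the group attribute, the "double
#' forest" variant of the virtual-twins literature; defaults 500 trees
#' each, the regression-forest `mtry = p/3` over the one-hot columns, and
#' `min.node.size` = 2% of the group's rows (at least 10) — probability
#' estimation behaves like regression, wanting larger terminal nodes and a
#' richer feature sample per split than classification; set
#' `params$per_group = FALSE` for a single pooled forest, optionally with
#' explicit group-by-covariate interaction features via
#' `params$interactions = TRUE`), `elastic_net`
#' (glmnet logistic regression, `alpha = 0.5`, lambda chosen by 5-fold
#' cross-validation), and `boosting_tree` (xgboost, 200 rounds, `eta = 0.1`,
#' `max_depth = 4`). Hyperparameters can be overridden through `params`.
#'
#' @param method family name (built-in or registered via
#'   [register_classifier()]).
#' @param params named list of hyperparameter overrides.
#' @param seed integer seed controlling all randomness in fitting.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("random_forest", "elastic_net",
                                       "boosting_tree"),
                            params = list(), seed = 1L) {
  if (length(method) == 1 && !method %in% c("random_forest", "elastic_net",
                                            "boosting_tree")) {
    classifier_entry(method) # errors if not registered
  } else {
    method <- match.arg(method)
  }
  structure(list(method = method, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

# ---- design-matrix encoding ------------------------------------------------

build_dictionary <- function(table, covariates) {
  dict <- lapply(table[covariates], function(x) {
    if (!is.factor(x)) x <- factor(x)
    list(levels = levels(x), ordered = is.ordered(x))
  })
  names(dict) <- covariates
  dict
}

encode_design <- function(table, covariates, dict, group, group_value = NULL) {
  n <- nrow(table)
  if (is.null(group_value)) {
    d <- group_indicator(table[[group]], group)
  } else {
    d <- rep(as.integer(group_value), n)
  }
  cols <- list(D = d)
  for (v in covariates) {
    x <- as.character(table[[v]])
    if (anyNA(x))
      vt_stop(sprintf("covariate '%s' has missing values", v),
              "vt_schema_error")
    lev <- dict[[v]]$levels
    bad <- setdiff(unique(x), lev)
    if (length(bad))
      vt_stop(sprintf("variable '%s' has unseen level '%s'", v, bad[1]),
              "vt_schema_error")
    for (l in lev) cols[[paste0(v, "=", l)]] <- as.integer(x == l)
  }
  mat <- do.call(cbind, cols)
  storage.mode(mat) <- "double"
  mat
}

design_variable_map <- function(colnames, group) {
  var <- sub("=.*$", "", colnames)
  var[colnames == "D"] <- group
  var
}

# ---- built-in families -----------------------------------------------------

# Random forest family. Default is the per-group ("double forest") variant
# of the virtual-twins literature: one probability forest per value of D,
# so the counterfactual difference does not rely on the forest finding deep
# group-by-covariate interaction splits — a single pooled forest smooths
# such interactions away at moderate training sizes. A pooled single forest
# (optionally with explicit D-by-covariate interaction features) is
# available via `params$per_group = FALSE` / `params$interactions = TRUE`.
.rf_one <- function(x, y, params, seed, min_node_default,
                    mtry_default = NULL) {
  ranger::ranger(
    x = x, y = factor(y, levels = c(0, 1)),
    probability = TRUE,
    num.trees = params$num_trees %||% 500,
    mtry = params$mtry %||% mtry_default %||% max(1, floor(sqrt(ncol(x)))),
    min.node.size = params$min_node_size %||% min_node_default,
    importance = "impurity",
    seed = seed, num.threads = 1)
}
.rf_interact <- function(x) {
  xi <- x[, -1, drop = FALSE] * x[, 1]
  colnames(xi) <- paste0("D:", colnames(x)[-1])
  cbind(x, xi)
}
.fit_random_forest <- function(x, y, params, seed) {
  if (isTRUE(params$per_group %||% TRUE)) {
    d <- x[, "D"]
    xc <- x[, colnames(x) != "D", drop = FALSE]
    # probability estimation is regression-like: larger terminal nodes
    # (2% of the group's rows, at least 10) and the regression-forest
    # mtry p/3 — with sqrt(p) over one-hot columns a split samples barely
    # one variable's worth of columns, which biases cell probabilities
    # toward their neighbours' means
    mnd <- function(n) max(10, ceiling(0.02 * n))
    # p/3 of the one-hot columns, but never fewer than a handful (or all,
    # for very small designs): tiny designs starve otherwise
    mtry <- max(ceiling(ncol(xc) / 3), min(ncol(xc), 8L))
    list(kind = "per_group",
         f1 = .rf_one(xc[d == 1, , drop = FALSE], y[d == 1], params, seed,
                      min_node_default = mnd(sum(d == 1)),
                      mtry_default = mtry),
         f0 = .rf_one(xc[d == 0, , drop = FALSE], y[d == 0], params,
                      seed + 1L, min_node_default = mnd(sum(d == 0)),
                      mtry_default = mtry))
  } else {
    xd <- if (isTRUE(params$interactions)) .rf_interact(x) else x
    list(kind = "pooled", interactions = isTRUE(params$interactions),
         f = .rf_one(xd, y, params, seed, min_node_default = 10))
  }
}
.predict_random_forest <- function(fit, x) {
  if (fit$kind == "pooled") {
    xd <- if (fit$interactions) .rf_interact(x) else x
    return(stats::predict(fit$f, data = xd,
                          num.threads = 1)$predictions[, "1"])
  }
  d <- x[, "D"]
  xc <- x[, colnames(x) != "D", drop = FALSE]
  p <- numeric(nrow(x))
  if (any(d == 1))
    p[d == 1] <- stats::predict(fit$f1, data = xc[d == 1, , drop = FALSE],
                                num.threads = 1)$predictions[, "1"]
  if (any(d == 0))
    p[d == 0] <- stats::predict(fit$f0, data = xc[d == 0, , drop = FALSE],
                                num.threads = 1)$predictions[, "1"]
  p
}
.importance_random_forest <- function(fit, cols) {
  if (fit$kind == "pooled") {
    imp <- ranger::importance(fit$f)
    return(pmax(imp[cols], 0))
  }
  # per-group forests condition on D by construction; covariate scores are
  # averaged across the two forests and D itself carries no impurity score
  i1 <- ranger::importance(fit$f1)
  i0 <- ranger::importance(fit$f0)
  out <- stats::setNames(rep(0, length(cols)), cols)
  shared <- setdiff(cols, "D")
  out[shared] <- pmax((i1[shared] + i0[shared]) / 2, 0)
  out
}

.fit_elastic_net <- function(x, y, params, seed) {
  set.seed(seed)
  glmnet::cv.glmnet(x, y, family = "binomial",
                    alpha = params$alpha %||% 0.5,
                    nfolds = params$nfolds %||% 5)
}
.predict_elastic_net <- function(fit, x) {
  as.numeric(stats::predict(fit, newx = x, s = "lambda.min",
                            type = "response"))
}
.importance_elastic_net <- function(fit, cols) {
  b <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1] # drop intercept
  names(b) <- rownames(stats::coef(fit, s = "lambda.min"))[-1]
  sds <- attr(fit, "vt_col_sd")
  abs(b[cols]) * (if (is.null(sds)) 1 else sds[cols])
}

.fit_boosting_tree <- function(x, y, params, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  eta = params$eta %||% 0.1,
                  max_depth = params$max_depth %||% 4,
                  nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
    nrounds = params$nrounds %||% 200, verbose = 0)
}
.predict_boosting_tree <- function(fit, x) {
  stats::predict(fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1))
}
.importance_boosting_tree <- function(fit, cols) {
  imp <- xgboost::xgb.importance(model = fit)
  out <- stats::setNames(rep(0, length(cols)), cols)
  out[imp$Feature] <- imp$Gain
  out
}

local({
  register_classifier("random_forest", .fit_random_forest,
                      .predict_random_forest, .importance_random_forest)
  register_classifier("elastic_net", .fit_elastic_net,
                      .predict_elastic_net, .importance_elastic_net)
  register_classifier("boosting_tree", .fit_boosting_tree,
                      .predict_boosting_tree, .importance_boosting_tree)
})

# ---- fitting and prediction ------------------------------------------------

#' Fit a wait-probability classifier
#'
#' Fits `P(Y = 1 | D, X)` on a training table with the group attribute
#' included among the predictors. Categorical covariates are one-hot encoded
#' against the factor dictionaries frozen in the training table, and the
#' fitted model refuses prediction inputs whose levels fall outside that
#' dictionary.
#'
#' @param train prepared training table.
#' @param spec a [classifier_spec()].
#' @param outcome,group column names of the binary outcome and group factor
#'   (the factor's second level is the focal group, `D = 1`).
#' @param covariates predictor columns; default: everything except outcome
#'   and group.
#' @return an object of class `wait_model`.
#' @export
fit_wait_model <- function(train, spec, outcome = "wait_binary",
                           group = "race", covariates = NULL) {
  if (!inherits(spec, "classifier_spec"))
    vt_stop("'spec' must be a classifier_spec", "vt_config_error")
  covariates <- covariates %||% setdiff(names(train), c(outcome, group))
  y <- train[[outcome]]
  if (length(unique(y)) < 2)
    vt_stop("training data contain a single outcome class", "vt_fit_error")
  dict <- build_dictionary(train, covariates)
  x <- encode_design(train, covariates, dict, group)
  entry <- classifier_entry(spec$method)
  fit <- entry$fit(x, as.integer(y), spec$params, spec$seed)
  if (spec$method == "elastic_net")
    attr(fit, "vt_col_sd") <- apply(x, 2, stats::sd)
  structure(list(fit = fit, spec = spec, dict = dict,
                 covariates = covariates, outcome = outcome, group = group,
                 design_cols = colnames(x),
                 fingerprint = paste(spec$method, spec$seed,
                                     digest_dict(dict), sep = ":")),
            class = "wait_model")
}

digest_dict <- function(dict) {
  s <- paste(vapply(names(dict), function(v)
    paste0(v, "{", paste(dict[[v]]$levels, collapse = "|"), "}"),
    character(1)), collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  format(h, scientific = FALSE)
}

#' Predict the wait probability, optionally counterfactually
#'
#' Scores episodes under a fixed value of the group attribute, regardless of
#' each episode's actual group: the counterfactual scoring at the heart of
#' the virtual-twins procedure.
#'
#' @param model a fitted [fit_wait_model()] object.
#' @param group_value 0 or 1 (`NULL`: use each row's actual group).
#' @param newdata episode table matching the training schema.
#' @return numeric probabilities in `[0, 1]`.
#' @export
predict_wait_probability <- function(model, group_value = NULL, newdata) {
  if (!inherits(model, "wait_model"))
    vt_stop("'model' must be a wait_model", "vt_config_error")
  if (!is.null(group_value) && !group_value %in% c(0, 1))
    vt_stop("'group_value' must be 0 or 1", "vt_config_error")
  x <- encode_design(newdata, model$covariates, model$dict, model$group,
                     group_value)
  entry <- classifier_entry(model$spec$method)
  p <- entry$predict(model$fit, x)
  if (any(!is.finite(p)) || any(p < -1e-12) || any(p > 1 + 1e-12))
    vt_stop("classifier returned probabilities outside [0, 1]",
            "vt_fit_error")
  pmin(pmax(p, 0), 1)
}

#' @export
predict.wait_model <- function(object, newdata, group_value = NULL, ...) {
  predict_wait_probability(object, group_value, newdata)
}

#' @export
print.wait_model <- function(x, ...) {
  cat(sprintf("Wait-probability model (%s), %d predictors, outcome '%s'\n",
              x$spec$method, length(x$covariates) + 1L, x$outcome))
  cat("  schema fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

#' Variable-level importance scores
#'
#' Aggregates design-column importances (impurity decrease for tree-based
#' families; absolute standardized coefficients for the elastic net) to one
#' non-negative score per input variable, including the group attribute,
#' sorted in decreasing order.
#'
#' @param model a `wait_model`.
#' @return `data.frame` with columns `variable`, `importance`.
#' @export
variable_importance <- function(model) {
  entry <- classifier_entry(model$spec$method)
  if (is.null(entry$importance))
    vt_stop(sprintf("classifier family '%s' does not support importance",
                    model$spec$method), "vt_capability_error")
  sc <- entry$importance(model$fit, model$design_cols)
  sc[is.na(sc)] <- 0
  var <- design_variable_map(model$design_cols, model$group)
  agg <- tapply(as.numeric(sc), var, sum)
  out <- data.frame(variable = names(agg), importance = as.numeric(agg))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

#' Save or load a fitted wait model
#'
#' Serializes the fitted model together with a format version and its
#' training-schema fingerprint; loading refuses artifacts whose version is
#' unknown, and the fingerprint lets callers verify that a model matches
#' the table they are about to score.
#'
#' @param model a `wait_model`.
#' @param path artifact path (binary RDS).
#' @export
save_wait_model <- function(model, path) {
  if (!inherits(model, "wait_model"))
    vt_stop("'model' must be a wait_model", "vt_config_error")
  saveRDS(list(format = "vtdisparity-wait-model/1", model = model), path)
  invisible(path)
}

#' @rdname save_wait_model
#' @return `load_wait_model` returns the restored `wait_model`.
#' @export
load_wait_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "vtdisparity-wait-model/1"))
    vt_stop("not a recognized wait-model artifact", "vt_config_error")
  x$model
}

# ---- repeated-split comparison harness -------------------------------------

#' Compare classifier families under repeated random splits
#'
#' For each replicate the table is split into a training fraction and a test
#' remainder; every spec is fitted on the training part and scored on the
#' test part. Reported per spec: mean and SD over replicates of the overall,
#' focal-group (`D = 1`) and reference-group (`D = 0`) misclassification
#' percentages (threshold 0.5, ties to class 0) and the rank-statistic AUC.
#' A replicate whose training part lacks an outcome class is resampled.
#'
#' @param table prepared analytic table.
#' @param specs list of [classifier_spec()]s.
#' @param n_reps number of replicates.
#' @param train_frac training fraction per split (the harness convention is
#'   to train on the smaller part and test on the remainder).
#' @param seed master seed; per-replicate split and fit seeds derive from it.
#' @param outcome,group column names.
#' @return an object of class `model_comparison`: summary `data.frame` plus
#'   per-replicate metrics in attribute `replicates`.
#' @export
compare_classifiers <- function(table, specs, n_reps = 100, train_frac = 0.2,
                                seed = 1L, outcome = "wait_binary",
                                group = "race") {
  if (n_reps < 1) vt_stop("'n_reps' must be >= 1", "vt_config_error")
  if (train_frac <= 0 || train_frac >= 1)
    vt_stop("'train_frac' must lie in (0, 1)", "vt_config_error")
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  methods <- vapply(specs, function(s) s$method, character(1))
  d_all <- group_indicator(table[[group]], group)
  reps <- list()
  for (r in seq_len(n_reps)) {
    attempt <- 0L
    repeat {
      split_seed <- derive_seed(seed, sprintf("rep%d.%d", r, attempt))
      parts <- split_once(table, train_frac, split_seed)
      if (length(unique(parts$train[[outcome]])) == 2) break
      attempt <- attempt + 1L
      message(sprintf("replicate %d: single-class training split, resampling",
                      r))
      if (attempt > 100)
        vt_stop("could not draw a two-class training split", "vt_fit_error")
    }
    test_y <- as.integer(parts$estimation[[outcome]])
    test_d <- d_all[parts$estimation_idx]
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      sp$seed <- derive_seed(seed, sprintf("fit%d.%d", r, k))
      fit <- fit_wait_model(parts$train, sp, outcome, group)
      p <- predict_wait_probability(fit, NULL, parts$estimation)
      pred <- as.integer(p > 0.5)
      reps[[length(reps) + 1L]] <- data.frame(
        rep = r, method = methods[k],
        mis_overall = 100 * mean(pred != test_y),
        mis_group1 = 100 * mean(pred[test_d == 1] != test_y[test_d == 1]),
        mis_group0 = 100 * mean(pred[test_d == 0] != test_y[test_d == 0]),
        auc = rank_auc(p, test_y),
        n_test = length(test_y), n_group1 = sum(test_d == 1))
    }
  }
  reps <- do.call(rbind, reps)
  agg <- function(col, f) as.numeric(tapply(reps[[col]], reps$method, f))
  methods_u <- sort(unique(reps$method))
  idx <- match(methods_u, sort(unique(reps$method)))
  summary_df <- data.frame(
    method = methods_u,
    mis_overall_mean = agg("mis_overall", mean)[idx],
    mis_overall_sd = agg("mis_overall", stats::sd)[idx],
    mis_group1_mean = agg("mis_group1", mean)[idx],
    mis_group1_sd = agg("mis_group1", stats::sd)[idx],
    mis_group0_mean = agg("mis_group0", mean)[idx],
    mis_group0_sd = agg("mis_group0", stats::sd)[idx],
    auc_mean = agg("auc", mean)[idx],
    auc_sd = agg("auc", stats::sd)[idx])
  structure(list(summary = summary_df, n_reps = n_reps,
                 train_frac = train_frac),
            replicates = reps, class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Classifier comparison: %d replicates, train fraction %.2f\n",
    x$n_reps, x$train_frac))
  s <- x$summary
  fmt <- function(m, s) sprintf("%.*f (%.*f)", digits, m, digits, s)
  show <- data.frame(
    method = s$method,
    `mis% overall` = fmt(s$mis_overall_mean, s$mis_overall_sd),
    `mis% D=1` = fmt(s$mis_group1_mean, s$mis_group1_sd),
    `mis% D=0` = fmt(s$mis_group0_mean, s$mis_group0_sd),
    AUC = fmt(s$auc_mean, s$auc_sd), check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Export a model-comparison report as a delimited table
#'
#' @param report a `model_comparison`.
#' @param path output CSV path.
#' @export
write_comparison_report <- function(report, path) {
  utils::write.csv(report$summary, path, row.names = FALSE)
  invisible(path)
}
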