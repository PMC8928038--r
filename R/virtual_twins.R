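#' Split an episode table once into training and estimation parts
#'
#' Simple random sampling without stratification (optionally stratified by
#' outcome). The two parts are disjoint and exhaustive.
#'
#' @param table episode `data.frame` with at least 2 rows.
#' @param train_frac fraction assigned to the training part.
#' @param seed integer seed.
#' @param stratify_by optional column name; when given, sampling is carried
#'   out within each level so both parts keep the column's composition.
#' @return list with `train`, `estimation`, `train_idx`, `estimation_idx`.
#' @export
split_once <- function(table, train_frac = 0.2, seed = 1L,
                       stratify_by = NULL) {
  n <- nrow(table)
  if (n < 2) vt_stop("need at least 2 rows to split", "vt_split_error")
  if (train_frac <= 0 || train_frac >= 1)
    vt_stop("'train_frac' must lie in (0, 1)", "vt_config_error")
  set.seed(seed)
  if (is.null(stratify_by)) {
    k <- min(max(round(train_frac * n), 1L), n - 1L)
    train_idx <- sort(sample.int(n, k))
  } else {
    g <- table[[stratify_by]]
    train_idx <- sort(unlist(lapply(split(seq_len(n), g), function(ix) {
      k <- round(train_frac * length(ix))
      if (length(ix) == 0) return(integer(0))
      sample(ix, min(max(k, 0L), length(ix)))
    }), use.names = FALSE))
    if (length(train_idx) == 0 || length(train_idx) == n)
      vt_stop("stratified split produced an empty partition",
              "vt_split_error")
  }
  estimation_idx <- setdiff(seq_len(n), train_idx)
  list(train = table[train_idx, , drop = FALSE],
       estimation = table[estimation_idx, , drop = FALSE],
       train_idx = train_idx, estimation_idx = estimation_idx)
}

#' Compute per-episode virtual probability differences
#'
#' For every estimation row, scores the Step-1 model under both values of
#' the group attribute and returns
#' \eqn{Z_i = P(Y=1 | D=1, X_i) - P(Y=1 | D=0, X_i)} — the extra probability
#' of the adverse outcome attributable solely to focal-group membership at
#' those covariates, irrespective of the episode's actual group.
#'
#' @param model a fitted [fit_wait_model()] object.
#' @param estimation episode table matching the model's training schema.
#' @return numeric vector in `[-1, 1]`, aligned with the rows of
#'   `estimation`; the model fingerprint is attached as an attribute.
#' @export
compute_virtual_differences <- function(model, estimation) {
  p1 <- predict_wait_probability(model, 1, estimation)
  p0 <- predict_wait_probability(model, 0, estimation)
  z <- p1 - p0
  if (any(!is.finite(z)))
    vt_stop("non-finite virtual differences", "vt_fit_error")
  attr(z, "fingerprint") <- model$fingerprint
  z
}

#' Two-step virtual-twins subgroup analysis
#'
#' Runs the full procedure on a prepared analytic table: (1) one random
#' split into a training part (`train_frac`, default 20%) and an estimation
#' part; (2) a probability classifier for the outcome given group and
#' covariates, fitted on the training part; (3) counterfactual virtual
#' differences `Z` on the estimation part; (4) a CART regression tree on
#' `(X without the group attribute, Z)` over the estimation rows; (5) rule
#' extraction and selection of the most vulnerable subgroup (maximal leaf
#' mean `Z`). A single split is used — the point of the final run is one
#' interpretable tree; use [compare_classifiers()] for replicate-based model
#' evaluation.
#'
#' @param data prepared analytic table (see [prepare_analytic_table()]).
#' @param outcome,group column names of the binary outcome and two-level
#'   group factor (second level = focal group).
#' @param spec a [classifier_spec()] for Step 1.
#' @param params a [tree_params()] for Step 2.
#' @param train_frac Step-1 training fraction.
#' @param min_coverage minimum leaf coverage for subgroup selection.
#' @param seed master seed; split and fit seeds are derived from it.
#' @param require_split error if the tree degenerates to a single leaf.
#' @param stratify_by optional stratification column for the split.
#' @return an object of class `virtual_twins` with components `model`
#'   (Step-1 fit), `z`, `tree`, `rules`, `selected`, split indices and
#'   seeds. Methods: `print`, `summary`, `predict` (Z for new episodes),
#'   `plot` (the tree).
#' @examples
#' cfg <- default_generator_config(n_episodes = 2000)
#' tab <- generate_episodes(cfg, seed = 1)
#' fit <- virtual_twins(tab, spec = classifier_spec("random_forest",
#'                                                  list(num_trees = 50)),
#'                      seed = 1)
#' print(fit)
#' @export
virtual_twins <- function(data, outcome = "wait_binary", group = "race",
                          spec = classifier_spec("random_forest"),
                          params = tree_params(), train_frac = 0.2,
                          min_coverage = 0.01, seed = 1L,
                          require_split = FALSE, stratify_by = NULL) {
  split_seed <- derive_seed(seed, "split")
  parts <- split_once(data, train_frac, split_seed, stratify_by)
  if (length(unique(parts$train[[outcome]])) < 2)
    vt_stop("training split contains a single outcome class",
            "vt_fit_error")
  fit_spec <- spec
  fit_spec$seed <- derive_seed(seed, paste0("fit.", spec$seed))
  model <- fit_wait_model(parts$train, fit_spec, outcome, group)
  z <- compute_virtual_differences(model, parts$estimation)
  X <- parts$estimation[setdiff(model$covariates, group)]
  tree <- fit_regression_tree(X, as.numeric(z), params, forbidden = group)
  rules <- extract_subgroup_rules(tree)
  if (require_split && length(rules) == 1)
    vt_stop("regression tree degenerated to a single leaf",
            "vt_fit_error")
  selected <- select_most_vulnerable(rules, min_coverage)
  structure(list(call = match.call(), model = model, z = z, tree = tree,
                 rules = rules, selected = selected,
                 outcome = outcome, group = group,
                 train_frac = train_frac, min_coverage = min_coverage,
                 n_train = nrow(parts$train),
                 n_estimation = nrow(parts$estimation),
                 train_idx = parts$train_idx,
                 estimation_idx = parts$estimation_idx,
                 seeds = c(master = seed, split = split_seed,
                           fit = fit_spec$seed)),
            class = "virtual_twins")
}

#' @export
print.virtual_twins <- function(x, ...) {
  cat("Virtual-twins subgroup analysis\n")
  cat(sprintf("  Step 1: %s on %d episodes (train fraction %.2f)\n",
              x$model$spec$method, x$n_train, x$train_frac))
  cat(sprintf("  Step 2: regression tree on Z over %d episodes, %d leaves\n",
              x$n_estimation, length(x$rules)))
  cat(sprintf("  Z: mean %+.4f, range [%+.4f, %+.4f]\n", mean(x$z),
              min(x$z), max(x$z)))
  cat("  Most vulnerable subgroup:\n    ", format(x$selected), "\n")
  invisible(x)
}

#' @export
summary.virtual_twins <- function(object, ...) {
  structure(list(fit = object), class = "summary.virtual_twins")
}

#' @export
print.summary.virtual_twins <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$fit$tree)
  cat("\n")
  print(x$fit$rules)
  invisible(x)
}

#' @export
predict.virtual_twins <- function(object, newdata,
                                  type = c("z", "leaf"), ...) {
  type <- match.arg(type)
  if (type == "z") return(compute_virtual_differences(object$model, newdata))
  route_to_leaves(object$tree, newdata)
}

#' @export
plot.virtual_twins <- function(x, ...) {
  plot(x$tree, ...)
}

#' Serialize a virtual-twins result as a structured text report
#'
#' @param fit a `virtual_twins` object.
#' @param path output path for the text report.
#' @param dot_path optional path for the Graphviz DOT rendering of the tree.
#' @export
write_vt_report <- function(fit, path, dot_path = NULL) {
  lines <- c(
    "virtual twins run report",
    sprintf("step1_method: %s", fit$model$spec$method),
    sprintf("model_fingerprint: %s", fit$model$fingerprint),
    sprintf("seeds: master=%d split=%d fit=%d", fit$seeds["master"],
            fit$seeds["split"], fit$seeds["fit"]),
    sprintf("train_frac: %g", fit$train_frac),
    sprintf("n_train: %d", fit$n_train),
    sprintf("n_estimation: %d", fit$n_estimation),
    sprintf("z_mean: %.6f", mean(fit$z)),
    sprintf("z_min: %.6f", min(fit$z)),
    sprintf("z_max: %.6f", max(fit$z)),
    sprintf("n_leaves: %d", length(fit$rules)),
    "tree:",
    render_tree(fit$tree, "text"),
    "rules:",
    vapply(fit$rules, function(r) paste0("  leaf ", r$leaf_id, ": ",
                                         format(r)), character(1)),
    "selected_rule:",
    paste0("  ", format(fit$selected)))
  writeLines(lines, path)
  if (!is.null(dot_path)) writeLines(render_tree(fit$tree, "dot"), dot_path)
  invisible(path)
}
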