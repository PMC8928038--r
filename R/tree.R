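# CART-style regression tree on the virtual probability difference Z.
# Split criterion: SSE reduction. Categorical splits use the mean-ordering
# contiguous scan, which attains the optimal bipartition under squared-error
# loss; ordinal variables split by threshold on the level order.

#' Regression-tree hyperparameters
#'
#' @param max_depth maximum tree depth (root = depth 0); at least 1.
#' @param min_split minimum rows in a node to attempt a split; default
#'   `2 * min_leaf`, resolved at fit time.
#' @param min_leaf minimum rows per leaf; default 1% of the fitting rows,
#'   resolved at fit time.
#' @param min_gain minimum absolute SSE reduction for a split.
#' @param cp complexity threshold: a split must additionally reduce SSE by
#'   at least `cp` times the root-node SSE (the CART growth default, 0.01).
#'   Set to 0 to grow on `min_gain` alone.
#' @param seed seed recorded for tie-breaking audits (splitting itself is
#'   deterministic; ties prefer the variable earlier in column order, then
#'   the smaller satisfying subset).
#' @return an object of class `tree_params`.
#' @export
tree_params <- function(max_depth = 4L, min_split = NULL, min_leaf = NULL,
                        min_gain = 0, cp = 0.01, seed = NULL) {
  if (max_depth < 1) vt_stop("'max_depth' must be >= 1", "vt_config_error")
  if (!is.null(min_leaf) && min_leaf < 1)
    vt_stop("'min_leaf' must be >= 1", "vt_config_error")
  if (!is.null(min_split) && !is.null(min_leaf) && min_split < 2 * min_leaf)
    vt_stop("'min_split' must be >= 2 * min_leaf", "vt_config_error")
  if (min_gain < 0 || cp < 0)
    vt_stop("'min_gain' and 'cp' must be >= 0", "vt_config_error")
  structure(list(max_depth = as.integer(max_depth), min_split = min_split,
                 min_leaf = min_leaf, min_gain = min_gain, cp = cp,
                 seed = seed),
            class = "tree_params")
}

resolve_tree_params <- function(params, n) {
  params$min_leaf <- as.integer(params$min_leaf %||% max(1, ceiling(0.01 * n)))
  params$min_split <- as.integer(params$min_split %||% (2L * params$min_leaf))
  if (params$min_split < 2L * params$min_leaf)
    vt_stop("'min_split' must be >= 2 * min_leaf", "vt_config_error")
  params
}

node_sse <- function(z) sum((z - mean(z))^2)

# best contiguous cut after ordering groups; returns k (cut after position k)
# and gain. sums/ns are per ordered group. Gain = S_L^2/n_L + S_R^2/n_R - S^2/n.
best_cut <- function(sums, ns, min_leaf) {
  S <- sum(sums); N <- sum(ns)
  csum <- cumsum(sums); cn <- cumsum(ns)
  k <- seq_len(length(ns) - 1L)
  nl <- cn[k]; nr <- N - nl
  ok <- nl >= min_leaf & nr >= min_leaf
  if (!any(ok)) return(NULL)
  gain <- csum[k]^2 / nl + (S - csum[k])^2 / nr - S^2 / N
  gain[!ok] <- -Inf
  best <- which.max(gain)
  list(k = k[best], gain = gain[best], nl = nl[best], nr = nr[best])
}

#' Best single split of one covariate
#'
#' Finds the split condition of `x` maximizing the SSE reduction
#' \eqn{\Delta = SSE(parent) - SSE(left) - SSE(right)} of `z`, subject to the
#' minimum-leaf constraint. Categorical variables are searched by ordering
#' observed levels by mean `z` and scanning contiguous cut points (optimal
#' for squared-error loss); ordinal variables are scanned in level order, so
#' the left branch is always `<= threshold`.
#'
#' @param x one covariate (factor, ordered factor, or numeric).
#' @param z numeric response vector aligned with `x`.
#' @param params a [tree_params()]; `min_leaf`/`min_split`/`min_gain` are
#'   honored (`cp` applies only within [fit_regression_tree()]).
#' @param variable variable name recorded in the returned condition.
#' @return `NULL` if no admissible split attains `min_gain`, else a list
#'   with `condition` (class `split_condition`) and `gain`.
#' @export
best_split <- function(x, z, params = tree_params(), variable = "x") {
  if (any(!is.finite(z))) vt_stop("non-finite z values", "vt_data_error")
  params <- resolve_tree_params(params, length(z))
  if (length(z) < params$min_split) return(NULL)
  min_gain <- params$min_gain
  if (is.numeric(x) || is.ordered(x)) {
    xo <- if (is.numeric(x)) x else as.integer(x)
    vals <- sort(unique(xo))
    if (length(vals) < 2) return(NULL)
    grp <- match(xo, vals)
    sums <- as.numeric(tapply(z, grp, sum))
    ns <- as.integer(tabulate(grp, length(vals)))
    cut <- best_cut(sums, ns, params$min_leaf)
    if (is.null(cut) || cut$gain < min_gain || cut$gain <= 0) return(NULL)
    thr_idx <- vals[cut$k]
    cond <- structure(list(variable = variable, kind = "ordinal",
                           threshold = thr_idx,
                           threshold_label = if (is.ordered(x))
                             levels(x)[thr_idx] else as.character(thr_idx)),
                      class = "split_condition")
    return(list(condition = cond, gain = cut$gain))
  }
  if (!is.factor(x)) x <- factor(x)
  obs <- droplevels(x)
  if (nlevels(obs) < 2) return(NULL)
  means <- tapply(z, obs, mean)
  ord <- order(means, na.last = NA)
  lev_sorted <- levels(obs)[ord]
  grp <- match(as.character(obs), lev_sorted)
  sums <- as.numeric(tapply(z, grp, sum))
  ns <- as.integer(tabulate(grp, length(lev_sorted)))
  cut <- best_cut(sums, ns, params$min_leaf)
  if (is.null(cut) || cut$gain < min_gain || cut$gain <= 0) return(NULL)
  left_levels <- lev_sorted[seq_len(cut$k)]
  # canonical orientation: the satisfying subset is the smaller one (ties:
  # the one containing the alphabetically first level), for deterministic
  # output
  right_levels <- setdiff(lev_sorted, left_levels)
  satisfied <- if (length(left_levels) < length(right_levels)) left_levels
  else if (length(right_levels) < length(left_levels)) right_levels
  else if (min(left_levels) <= min(right_levels)) left_levels
  else right_levels
  cond <- structure(list(variable = variable, kind = "categorical",
                         levels = sort(satisfied)),
                    class = "split_condition")
  list(condition = cond, gain = cut$gain)
}

condition_satisfied <- function(cond, table) {
  x <- table[[cond$variable]]
  if (is.null(x))
    vt_stop(sprintf("variable '%s' not found", cond$variable),
            "vt_schema_error")
  if (cond$kind == "ordinal") {
    xo <- if (is.numeric(x)) x else as.integer(x)
    xo <= cond$threshold
  } else {
    if (is.factor(x)) {
      bad <- setdiff(cond$levels, levels(x))
      if (length(bad))
        vt_stop(sprintf("condition level '%s' unknown for variable '%s'",
                        bad[1], cond$variable), "vt_schema_error")
    }
    as.character(x) %in% cond$levels
  }
}

format_condition <- function(cond, negated = FALSE) {
  if (cond$kind == "ordinal") {
    op <- if (negated) ">" else "<="
    sprintf("%s %s %s", cond$variable, op, cond$threshold_label)
  } else {
    op <- if (negated) "not in" else "in"
    sprintf("%s %s {%s}", cond$variable, op,
            paste(cond$levels, collapse = ", "))
  }
}

#' Fit a regression tree on the virtual probability difference
#'
#' Greedy recursive partitioning: at each node, [best_split()] is evaluated
#' for every covariate and the largest admissible SSE reduction wins (exact
#' ties prefer the variable earlier in column order, then the smaller
#' satisfying subset). Growth stops on `max_depth`, node size, or when no
#' split attains `max(min_gain, cp * SSE(root))`. Leaves predict the mean
#' `z` of their rows. The left child always holds the rows satisfying the
#' node's condition. The group attribute must not be among the covariates;
#' a column named `race` (or matching `forbidden`) is a contract violation.
#'
#' @param X `data.frame` of covariates (no group/outcome columns).
#' @param z numeric response (per-episode virtual difference).
#' @param params a [tree_params()].
#' @param forbidden column names that must not appear in `X`.
#' @return an object of class `subgroup_tree`.
#' @export
fit_regression_tree <- function(X, z, params = tree_params(),
                                forbidden = "race") {
  if (!is.data.frame(X)) X <- as.data.frame(X)
  bad <- intersect(forbidden, names(X))
  if (length(bad))
    vt_stop(sprintf("'%s' must not be a tree covariate", bad[1]),
            "vt_contract_error")
  if (nrow(X) != length(z))
    vt_stop("covariate rows and z length differ", "vt_data_error")
  if (any(!is.finite(z))) vt_stop("non-finite z values", "vt_data_error")
  n <- length(z)
  params <- resolve_tree_params(params, n)
  root_sse <- node_sse(z)
  gain_floor <- max(params$min_gain, params$cp * root_sse)
  nodes <- list()

  grow <- function(idx, depth, id) {
    zi <- z[idx]
    node <- list(id = id, depth = depth, n = length(idx),
                 mean = mean(zi), sse = node_sse(zi),
                 coverage = length(idx) / n, split = NULL,
                 children = NULL)
    if (depth < params$max_depth && length(idx) >= params$min_split) {
      best <- NULL
      for (v in names(X)) {
        cand <- best_split(X[[v]][idx], zi, params, variable = v)
        if (is.null(cand)) next
        if (is.null(best) || cand$gain > best$gain + 1e-12) best <- cand
        else if (abs(cand$gain - best$gain) <= 1e-12) {
          # same gain: keep earlier variable (current loop order), i.e. do
          # nothing; within a variable best_split already prefers the
          # canonical smaller subset
        }
      }
      if (!is.null(best) && best$gain >= gain_floor && best$gain > 0) {
        sat <- condition_satisfied(best$condition, X[idx, , drop = FALSE])
        node$split <- best$condition
        node$gain <- best$gain
        node$children <- c(2L * id, 2L * id + 1L)
        nodes[[as.character(id)]] <<- node
        grow(idx[sat], depth + 1L, 2L * id)
        grow(idx[!sat], depth + 1L, 2L * id + 1L)
        return(invisible(NULL))
      }
    }
    nodes[[as.character(id)]] <<- node
    invisible(NULL)
  }
  grow(seq_len(n), 0L, 1L)
  structure(list(nodes = nodes, params = params, n = n,
                 root_sse = root_sse, var_names = names(X)),
            class = "subgroup_tree")
}

tree_leaves <- function(tree) {
  Filter(function(nd) is.null(nd$split), tree$nodes)
}

#' Route rows of a table to tree leaves
#'
#' @param tree a `subgroup_tree`.
#' @param X covariate `data.frame`.
#' @return integer vector of leaf node ids, one per row.
#' @export
route_to_leaves <- function(tree, X) {
  out <- integer(nrow(X))
  assign_node <- function(idx, id) {
    nd <- tree$nodes[[as.character(id)]]
    if (is.null(nd$split)) {
      out[idx] <<- id
      return(invisible(NULL))
    }
    sat <- condition_satisfied(nd$split, X[idx, , drop = FALSE])
    assign_node(idx[sat], nd$children[1])
    assign_node(idx[!sat], nd$children[2])
  }
  assign_node(seq_len(nrow(X)), 1L)
  out
}

#' Extract one subgroup rule per leaf
#'
#' A rule is the conjunction of conditions along the root-to-leaf path, each
#' marked satisfied (left branch) or violated (right branch). The rules are
#' mutually exclusive and exhaustive over the covariate space.
#'
#' @param tree a `subgroup_tree`.
#' @return an object of class `subgroup_rules`: list of `subgroup_rule`s,
#'   each with `conditions` (list of `(condition, negated)`), `mean_z`, `n`,
#'   `coverage`, and `leaf_id`, in left-to-right leaf order.
#' @export
extract_subgroup_rules <- function(tree) {
  rules <- list()
  walk <- function(id, path) {
    nd <- tree$nodes[[as.character(id)]]
    if (is.null(nd$split)) {
      rules[[length(rules) + 1L]] <<- structure(
        list(conditions = path, mean_z = nd$mean, n = nd$n,
             coverage = nd$coverage, leaf_id = nd$id),
        class = "subgroup_rule")
      return(invisible(NULL))
    }
    walk(nd$children[1],
         c(path, list(list(condition = nd$split, negated = FALSE))))
    walk(nd$children[2],
         c(path, list(list(condition = nd$split, negated = TRUE))))
  }
  walk(1L, list())
  structure(rules, class = "subgroup_rules")
}

rule_variables <- function(rule) {
  unique(vapply(rule$conditions, function(cn) cn$condition$variable,
                character(1)))
}

# merge a path's conditions per variable for display: categorical
# conditions intersect their satisfying sets (minus negated sets); ordinal
# conditions keep the tightest bounds. Rule structure is left untouched.
merge_rule_conditions <- function(conditions) {
  info <- list()
  order_seen <- character(0)
  for (cn in conditions) {
    v <- cn$condition$variable
    if (!v %in% order_seen) order_seen <- c(order_seen, v)
    st <- info[[v]] %||% list(kind = cn$condition$kind, allowed = NULL,
                              excluded = character(0), lo = NULL, hi = NULL,
                              lo_lab = NULL, hi_lab = NULL)
    if (cn$condition$kind == "categorical") {
      if (cn$negated) {
        st$excluded <- union(st$excluded, cn$condition$levels)
      } else {
        st$allowed <- if (is.null(st$allowed)) cn$condition$levels
        else intersect(st$allowed, cn$condition$levels)
      }
    } else {
      if (cn$negated) { # > threshold
        if (is.null(st$lo) || cn$condition$threshold > st$lo) {
          st$lo <- cn$condition$threshold
          st$lo_lab <- cn$condition$threshold_label
        }
      } else {          # <= threshold
        if (is.null(st$hi) || cn$condition$threshold < st$hi) {
          st$hi <- cn$condition$threshold
          st$hi_lab <- cn$condition$threshold_label
        }
      }
    }
    info[[v]] <- st
  }
  out <- character(0)
  for (v in order_seen) {
    st <- info[[v]]
    if (st$kind == "categorical") {
      allowed <- if (!is.null(st$allowed)) setdiff(st$allowed, st$excluded)
      if (!is.null(allowed)) {
        out <- c(out, sprintf("%s in {%s}", v,
                              paste(sort(allowed), collapse = ", ")))
      } else if (length(st$excluded)) {
        out <- c(out, sprintf("%s not in {%s}", v,
                              paste(sort(st$excluded), collapse = ", ")))
      }
    } else {
      if (!is.null(st$lo))
        out <- c(out, sprintf("%s > %s", v, st$lo_lab))
      if (!is.null(st$hi))
        out <- c(out, sprintf("%s <= %s", v, st$hi_lab))
    }
  }
  out
}

#' @export
format.subgroup_rule <- function(x, ...) {
  if (length(x$conditions) == 0) conds <- "(all episodes)"
  else conds <- paste(merge_rule_conditions(x$conditions), collapse = " AND ")
  sprintf("%s  ->  mean Z = %+.4f, n = %d (%.0f%%)", conds, x$mean_z, x$n,
          100 * x$coverage)
}

#' @export
print.subgroup_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
print.subgroup_rules <- function(x, ...) {
  cat("Subgroup rules (one per leaf):\n")
  for (r in x) cat("  leaf", r$leaf_id, ":", format(r), "\n")
  invisible(x)
}

#' Select the most vulnerable subgroup
#'
#' Among rules with coverage at least `min_coverage`, returns the rule with
#' the largest leaf mean `Z`; ties prefer larger coverage, then the
#' left-most leaf in path order.
#'
#' @param rules a `subgroup_rules` list.
#' @param min_coverage minimum leaf coverage fraction.
#' @return the selected `subgroup_rule`.
#' @export
select_most_vulnerable <- function(rules, min_coverage = 0) {
  if (length(rules) == 0) vt_stop("no rules supplied", "vt_config_error")
  cov <- vapply(rules, function(r) r$coverage, numeric(1))
  keep <- which(cov >= min_coverage)
  if (length(keep) == 0)
    vt_stop("all rules fall below 'min_coverage'", "vt_selection_error")
  mz <- vapply(rules, function(r) r$mean_z, numeric(1))
  leaf <- vapply(rules, function(r) r$leaf_id, integer(1))
  ord <- keep[order(-mz[keep], -cov[keep], seq_along(keep))]
  rules[[ord[1]]]
}

#' Render a regression tree as text or Graphviz DOT
#'
#' Internal nodes show their split condition; the left child holds the rows
#' satisfying it. Leaves show mean `Z` to four decimals and their coverage
#' percentage (nearest integer), the display convention of subgroup-tree
#' figures in disparity analyses.
#'
#' @param tree a `subgroup_tree`.
#' @param format `"text"` or `"dot"`.
#' @return a character scalar (the rendering).
#' @export
render_tree <- function(tree, format = c("text", "dot")) {
  format <- match.arg(format)
  if (format == "text") {
    lines <- character(0)
    walk <- function(id, indent, branch) {
      nd <- tree$nodes[[as.character(id)]]
      pre <- paste0(strrep("  ", indent), branch)
      if (is.null(nd$split)) {
        lines <<- c(lines, sprintf("%sleaf %d: mean Z = %.4f (%d%%, n = %d)",
                                   pre, nd$id, nd$mean,
                                   round(100 * nd$coverage), nd$n))
      } else {
        lines <<- c(lines, sprintf("%snode %d: %s  [mean Z = %.4f, %d%%]",
                                   pre, nd$id, format_condition(nd$split),
                                   nd$mean, round(100 * nd$coverage)))
        walk(nd$children[1], indent + 1L, "yes: ")
        walk(nd$children[2], indent + 1L, "no:  ")
      }
    }
    walk(1L, 0L, "")
    return(paste(lines, collapse = "\n"))
  }
  esc <- function(s) gsub("\"", "\\\\\"", s)
  lines <- c("digraph subgroup_tree {", "  node [shape=box];")
  for (nd in tree$nodes) {
    if (is.null(nd$split)) {
      lab <- sprintf("%.4f\\n%d%%", nd$mean, round(100 * nd$coverage))
      lines <- c(lines, sprintf("  n%d [label=\"%s\", style=filled, fillcolor=\"%s\"];",
                                nd$id, lab,
                                if (nd$mean > 0) "mistyrose" else "lightcyan"))
    } else {
      lines <- c(lines, sprintf("  n%d [label=\"%s\"];", nd$id,
                                esc(format_condition(nd$split))))
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", nd$id,
                         nd$children[1]),
                 sprintf("  n%d -> n%d [label=\"no\"];", nd$id,
                         nd$children[2]))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' @export
print.subgroup_tree <- function(x, ...) {
  nl <- length(tree_leaves(x))
  cat(sprintf("Regression tree on Z: %d leaves, %d rows\n", nl, x$n))
  cat(render_tree(x, "text"), "\n")
  invisible(x)
}

#' @export
predict.subgroup_tree <- function(object, newdata, ...) {
  ids <- route_to_leaves(object, newdata)
  vapply(as.character(ids), function(i) object$nodes[[i]]$mean, numeric(1),
         USE.NAMES = FALSE)
}

#' @export
plot.subgroup_tree <- function(x, main = "Subgroup regression tree", ...) {
  leaves <- tree_leaves(x)
  leaf_ids <- vapply(leaves, function(nd) nd$id, integer(1))
  # in-order x positions for leaves
  pos <- new.env(parent = emptyenv())
  counter <- 0
  assign_x <- function(id) {
    nd <- x$nodes[[as.character(id)]]
    if (is.null(nd$split)) {
      counter <<- counter + 1
      assign(as.character(id), counter, envir = pos)
      return(counter)
    }
    xl <- assign_x(nd$children[1])
    xr <- assign_x(nd$children[2])
    xm <- (xl + xr) / 2
    assign(as.character(id), xm, envir = pos)
    xm
  }
  assign_x(1L)
  depth_max <- max(vapply(x$nodes, function(nd) nd$depth, integer(1)))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, length(leaf_ids) + 0.5),
                        ylim = c(-depth_max - 0.5, 0.5))
  graphics::title(main = main)
  for (nd in x$nodes) {
    px <- get(as.character(nd$id), envir = pos)
    py <- -nd$depth
    if (!is.null(nd$split)) {
      for (side in 1:2) {
        ch <- nd$children[side]
        cx <- get(as.character(ch), envir = pos)
        graphics::segments(px, py - 0.08, cx, py - 0.92)
        graphics::text((px + cx) / 2, py - 0.5,
                       labels = if (side == 1) "yes" else "no", cex = 0.7)
      }
      graphics::text(px, py, labels = format_condition(nd$split), cex = 0.7)
    } else {
      graphics::text(px, py,
                     labels = sprintf("%.4f\n%d%%", nd$mean,
                                      round(100 * nd$coverage)),
                     cex = 0.75, font = 2,
                     col = if (nd$mean > 0) "firebrick" else "steelblue4")
    }
  }
  invisible(x)
}
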