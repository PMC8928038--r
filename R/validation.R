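#' Pooled two-proportion test with optional continuity correction
#'
#' Compares the outcome proportions of the two groups in a 2x2 contingency
#' table. With the correction on (the default), the statistic is
#' \deqn{z = \max(0, |p_1 - p_2| - c) / \sqrt{\hat p (1 - \hat p)
#'       (1/n_1 + 1/n_2)}, \quad c = \tfrac{1}{2}(1/n_1 + 1/n_2)}
#' with pooled \eqn{\hat p = (k_1 + k_2)/(n_1 + n_2)} and two-sided
#' \eqn{p = 2\Phi(-z)}; \eqn{z^2} equals the Yates-corrected 2x2 chi-square.
#' A pooled proportion of exactly 0 or 1 has no variance; such degenerate
#' tables return `p = 1` with a warning.
#'
#' @param k1,n1 adverse-outcome count and total for the focal group
#'   (`D = 1`).
#' @param k2,n2 count and total for the reference group.
#' @param correct apply the continuity correction.
#' @return an object of class `disparity_test` (also `htest`): `statistic`
#'   (the chi-square, i.e. `z^2`), `z`, `p.value`, `p_label` (the p-value
#'   formatted, with values below the double-precision floor reported as
#'   `"< 2.20e-16"`), and the group proportions in `estimate`.
#' @examples
#' two_proportion_test(117, 426, 920, 5084) # p ~ 2.77e-06
#' @export
two_proportion_test <- function(k1, n1, k2, n2, correct = TRUE) {
  if (n1 < 1 || n2 < 1) vt_stop("group totals must be >= 1", "vt_data_error")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    vt_stop("counts must satisfy 0 <= k <= n", "vt_data_error")
  p1 <- k1 / n1
  p2 <- k2 / n2
  phat <- (k1 + k2) / (n1 + n2)
  degenerate <- phat %in% c(0, 1)
  if (degenerate) {
    warning("pooled proportion is 0 or 1; test is degenerate (p = 1)")
    z <- 0
  } else {
    cc <- if (correct) 0.5 * (1 / n1 + 1 / n2) else 0
    z <- max(0, abs(p1 - p2) - cc) /
      sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pnorm(-z)
  structure(list(
    statistic = c("X-squared" = z^2), z = z, p.value = p,
    p_label = if (p < 2.2e-16) "< 2.20e-16" else format(p, digits = 3),
    estimate = c(p1 = p1, p2 = p2),
    counts = c(k1 = k1, n1 = n1, k2 = k2, n2 = n2),
    method = paste0("Two-sample proportion test",
                    if (correct) " with continuity correction"),
    alternative = "two.sided",
    data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)),
    class = c("disparity_test", "htest"))
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the significance level by the number of comparisons — here the
#' number of leaves of the fitted subgroup tree, since each leaf defines one
#' tested subgroup.
#'
#' @param alpha family-wise significance level in (0, 1).
#' @param n_leaves number of tree leaves (comparisons).
#' @return `alpha / n_leaves`.
#' @examples
#' bonferroni_threshold(0.05, 8) # 0.00625
#' @export
bonferroni_threshold <- function(alpha, n_leaves) {
  if (alpha <= 0 || alpha >= 1) vt_stop("'alpha' must lie in (0, 1)",
                                        "vt_config_error")
  if (n_leaves < 1) vt_stop("'n_leaves' must be >= 1", "vt_config_error")
  alpha / n_leaves
}

#' Select the rows of a table satisfying a subgroup rule
#'
#' @param rule a `subgroup_rule` (from [extract_subgroup_rules()]).
#' @param table episode `data.frame` containing the rule's variables.
#' @return the subset `data.frame` (all rows for an empty rule).
#' @export
apply_rule <- function(rule, table) {
  keep <- rule_mask(rule, table)
  table[keep, , drop = FALSE]
}

rule_mask <- function(rule, table) {
  keep <- rep(TRUE, nrow(table))
  for (cn in rule$conditions) {
    sat <- condition_satisfied(cn$condition, table)
    keep <- keep & (if (cn$negated) !sat else sat)
  }
  keep
}

#' Validate subgroup rules on the full episode table
#'
#' Applies every extracted rule to the full data, forms the group-by-outcome
#' contingency counts in each subgroup, and tests the two proportions with
#' the (continuity-corrected) pooled test at the Bonferroni threshold
#' `alpha / L`, `L` = number of evaluable rules (rules whose subgroup lacks
#' one of the groups are flagged non-evaluable and excluded from `L` with a
#' warning). A marginal (whole-table) comparison at level `alpha` is
#' appended, and a reversal flag records whether the selected subgroup's
#' proportion difference and the marginal difference have opposite signs —
#' the Simpson-style pattern in which the focal group appears advantaged
#' overall yet disadvantaged inside the identified subgroup.
#'
#' @param rules a `subgroup_rules` list or a fitted `virtual_twins` object
#'   (whose selected rule then drives the reversal flag).
#' @param table full prepared episode table.
#' @param alpha family-wise significance level.
#' @param outcome,group column names.
#' @param correct continuity correction for the proportion tests.
#' @param selected optional `subgroup_rule` used for the reversal flag;
#'   defaults to the rule with maximal mean `Z` (or the `virtual_twins`
#'   selection).
#' @return an object of class `subgroup_validation`: a `data.frame` with
#'   one row per rule plus a `marginal` row (counts, proportions, corrected
#'   chi-square, p, threshold, significance, selection and evaluability
#'   flags); attributes `reversal` and `alpha`.
#' @export
validate_subgroups <- function(rules, table, alpha = 0.05,
                               outcome = "wait_binary", group = "race",
                               correct = TRUE, selected = NULL) {
  if (inherits(rules, "virtual_twins")) {
    selected <- selected %||% rules$selected
    rules <- rules$rules
  }
  if (length(rules) == 0) vt_stop("need at least one rule",
                                  "vt_config_error")
  if (is.null(selected))
    selected <- select_most_vulnerable(rules, min_coverage = 0)
  y <- as.integer(table[[outcome]])
  d <- group_indicator(table[[group]], group)
  row_for <- function(mask, label) {
    k1 <- sum(y[mask & d == 1]); n1 <- sum(mask & d == 1)
    k2 <- sum(y[mask & d == 0]); n2 <- sum(mask & d == 0)
    evaluable <- n1 > 0 && n2 > 0
    if (evaluable) {
      tst <- two_proportion_test(k1, n1, k2, n2, correct)
      data.frame(rule = label, k1 = k1, n1 = n1, p1 = k1 / n1,
                 k2 = k2, n2 = n2, p2 = k2 / n2,
                 statistic = unname(tst$statistic), p_value = tst$p.value,
                 p_label = tst$p_label, evaluable = TRUE)
    } else {
      data.frame(rule = label, k1 = k1, n1 = n1, p1 = NA_real_,
                 k2 = k2, n2 = n2, p2 = NA_real_,
                 statistic = NA_real_, p_value = NA_real_,
                 p_label = NA_character_, evaluable = FALSE)
    }
  }
  rows <- lapply(seq_along(rules), function(i)
    row_for(rule_mask(rules[[i]], table),
            paste0("leaf_", rules[[i]]$leaf_id)))
  res <- do.call(rbind, rows)
  if (any(!res$evaluable))
    warning(sprintf(
      "%d rule(s) lack episodes from one group and are non-evaluable",
      sum(!res$evaluable)))
  L <- sum(res$evaluable)
  if (L == 0) vt_stop("no evaluable rules", "vt_data_error")
  res$threshold <- bonferroni_threshold(alpha, L)
  res$significant <- !is.na(res$p_value) & res$p_value < res$threshold
  marg <- row_for(rep(TRUE, nrow(table)), "marginal")
  marg$threshold <- alpha
  marg$significant <- marg$p_value < alpha
  sel_label <- paste0("leaf_", selected$leaf_id)
  res$selected <- res$rule == sel_label
  marg$selected <- FALSE
  out <- rbind(res, marg)
  rownames(out) <- NULL
  sel_row <- out[out$rule == sel_label, ]
  reversal <- nrow(sel_row) == 1 && sel_row$evaluable &&
    sign(sel_row$p1 - sel_row$p2) * sign(marg$p1 - marg$p2) < 0
  structure(out, reversal = reversal, alpha = alpha,
            class = c("subgroup_validation", "data.frame"))
}

#' @export
print.subgroup_validation <- function(x, digits = 3, ...) {
  needed <- c("rule", "k1", "n1", "p1", "k2", "n2", "p2", "statistic",
              "p_label", "significant", "selected")
  if (!all(needed %in% names(x))) return(NextMethod())
  cat(sprintf(
    "Subgroup validation (alpha = %g, Bonferroni threshold = %g)\n",
    attr(x, "alpha"), x$threshold[1]))
  show <- data.frame(
    rule = x$rule,
    `k1/n1` = sprintf("%d/%d", x$k1, x$n1),
    p1 = round(x$p1, digits),
    `k2/n2` = sprintf("%d/%d", x$k2, x$n2),
    p2 = round(x$p2, digits),
    chisq = signif(x$statistic, 4),
    p = x$p_label,
    significant = x$significant,
    selected = ifelse(x$selected, "*", ""),
    check.names = FALSE)
  print(show, row.names = FALSE)
  cat(sprintf("Reversal (selected subgroup vs marginal sign): %s\n",
              attr(x, "reversal")))
  invisible(x)
}

#' Export a validation table as delimited text
#'
#' @param validation a `subgroup_validation`.
#' @param path output CSV path.
#' @export
write_validation_table <- function(validation, path) {
  out <- as.data.frame(validation)
  out$reversal <- attr(validation, "reversal")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
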