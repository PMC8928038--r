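#' Configure conversion of raw episode tables to the analytic table
#'
#' @param wait_variable name of the raw wait-time column. Its values are
#'   ordinal bands such as `0`, `1-7`, `8-14`, `15-30`, `31+`, plus an
#'   unknown code; an already-dichotomized 0/1 column also works, with
#'   `wait_zero_level = "0"`.
#' @param wait_zero_level the band mapped to outcome class 0 (no wait);
#'   every other non-unknown band becomes class 1.
#' @param wait_unknown_level band treated as unknown wait; such rows are
#'   deleted.
#' @param race_variable name of the group column.
#' @param retained_races exactly two levels to keep, focal group first: rows
#'   with any other value are dropped, and the group factor is recoded with
#'   the reference group as level 1 and the focal group (`D = 1`) as level 2.
#' @param collapse_map optional named list: `collapse_map$var` is a named
#'   list mapping each new level to the character vector of old levels it
#'   absorbs (for categorical variables with too many levels).
#' @param drop_missing drop rows containing any missing covariate cell.
#' @return an object of class `prep_config`.
#' @export
prep_config <- function(wait_variable = "wait_binary",
                        wait_zero_level = "0",
                        wait_unknown_level = "Unknown",
                        race_variable = "race",
                        retained_races = c("African American", "White"),
                        collapse_map = list(),
                        drop_missing = TRUE) {
  if (length(retained_races) != 2 || anyDuplicated(retained_races))
    vt_stop("'retained_races' must be exactly two distinct levels",
            "vt_config_error")
  structure(list(wait_variable = wait_variable,
                 wait_zero_level = as.character(wait_zero_level),
                 wait_unknown_level = as.character(wait_unknown_level),
                 race_variable = race_variable,
                 retained_races = as.character(retained_races),
                 collapse_map = collapse_map,
                 drop_missing = isTRUE(drop_missing)),
            class = "prep_config")
}

#' Build the analytic episode table
#'
#' Applies, in order: deletion of rows with unknown wait, restriction to the
#' two retained race groups, deletion of rows with any missing covariate
#' cell (each row is counted in exactly one drop bucket, in that
#' precedence), dichotomization of the wait outcome (`wait_binary = 0` iff
#' the raw band equals `wait_zero_level`), group recoding, and category
#' collapsing. Factor dictionaries of the surviving covariates are frozen
#' here and shared by all downstream model fitting and counterfactual
#' scoring. The operation is idempotent: re-preparing an analytic table is a
#' no-op.
#'
#' @param raw raw episode `data.frame`.
#' @param prep a [prep_config()].
#' @return the analytic `data.frame` with integer `wait_binary`, the recoded
#'   group factor, and covariate factors; attribute `drop_counts` holds the
#'   per-bucket deletion counts.
#' @export
prepare_analytic_table <- function(raw, prep = prep_config()) {
  if (!inherits(prep, "prep_config"))
    vt_stop("'prep' must be a prep_config", "vt_config_error")
  wv <- prep$wait_variable
  if (!wv %in% names(raw)) {
    # idempotence: a table that already carries the binary outcome needs no
    # re-dichotomization
    if ("wait_binary" %in% names(raw)) wv <- "wait_binary"
    else vt_stop(sprintf("wait variable '%s' not found", wv),
                 "vt_schema_error")
  }
  rv <- prep$race_variable
  if (!rv %in% names(raw))
    vt_stop(sprintf("race variable '%s' not found", rv), "vt_schema_error")

  n_in <- nrow(raw)
  wait_raw <- as.character(raw[[wv]])
  keep1 <- !is.na(wait_raw) & wait_raw != prep$wait_unknown_level
  n_unknown_wait <- sum(!keep1)
  tab <- raw[keep1, , drop = FALSE]

  race_chr <- as.character(tab[[rv]])
  keep2 <- !is.na(race_chr) & race_chr %in% prep$retained_races
  n_race <- sum(!keep2)
  tab <- tab[keep2, , drop = FALSE]

  covnames <- setdiff(names(tab), c(wv, rv, "wait_binary"))
  if (prep$drop_missing && length(covnames)) {
    keep3 <- !Reduce(`|`, lapply(tab[covnames], is.na))
    n_missing <- sum(!keep3)
    tab <- tab[keep3, , drop = FALSE]
  } else n_missing <- 0L

  if (nrow(tab) == 0)
    vt_stop("no rows survive preparation", "vt_empty_error")

  y <- as.integer(as.character(tab[[wv]]) != prep$wait_zero_level)
  race <- factor(as.character(tab[[rv]]),
                 levels = rev(prep$retained_races)) # reference group first

  out <- tab[covnames]
  for (v in names(prep$collapse_map)) {
    if (!v %in% names(out))
      vt_stop(sprintf("collapse_map variable '%s' not found", v),
              "vt_schema_error")
    x <- as.character(out[[v]])
    old_levels <- levels(factor(out[[v]]))
    for (new in names(prep$collapse_map[[v]])) {
      olds <- prep$collapse_map[[v]][[new]]
      missing_lv <- setdiff(olds, unique(c(old_levels, x)))
      if (length(missing_lv))
        vt_stop(sprintf("collapse_map['%s']: level '%s' not found",
                        v, missing_lv[1]), "vt_schema_error")
      x[x %in% olds] <- new
    }
    out[[v]] <- factor(x)
  }
  # freeze dictionaries: keep declared levels even if unobserved
  for (v in names(out)) {
    if (!is.factor(out[[v]])) out[[v]] <- factor(out[[v]])
    out[[v]] <- droplevels(out[[v]], exclude = NULL)
    lv <- levels(raw[[v]])
    if (!is.null(lv) && !v %in% names(prep$collapse_map))
      out[[v]] <- factor(out[[v]], levels = lv,
                         ordered = is.ordered(raw[[v]]))
  }
  out <- cbind(data.frame(wait_binary = y, race = race), out)
  rownames(out) <- NULL
  structure(out,
            drop_counts = c(rows_in = n_in,
                            dropped_unknown_wait = n_unknown_wait,
                            dropped_race = n_race,
                            dropped_missing = n_missing,
                            rows_out = nrow(out)))
}

#' Descriptive comparison of covariates by outcome class
#'
#' For each covariate: level counts and within-class percentages split by
#' the binary outcome, with a chi-square test of independence (categorical,
#' uncorrected) or a two-sample t-test on integer level scores (ordinal).
#' No multiplicity correction is applied; this mirrors a descriptive
#' "Table 1" rather than confirmatory testing.
#'
#' @param table prepared analytic table (binary `wait_binary` present).
#' @param outcome outcome column name.
#' @return an object of class `descriptive_report`: list with `tables` (per
#'   variable count/percentage data frames) and `tests` (one row per
#'   variable: test name, statistic, df, p-value).
#' @export
descriptive_summary <- function(table, outcome = "wait_binary") {
  if (!outcome %in% names(table))
    vt_stop(sprintf("outcome '%s' not found", outcome), "vt_schema_error")
  y <- table[[outcome]]
  vars <- setdiff(names(table), outcome)
  tabs <- list()
  tests <- list()
  for (v in vars) {
    x <- table[[v]]
    counts <- table(factor(x), factor(y, levels = c(0, 1)))
    pct <- prop.table(counts, margin = 2) * 100
    tabs[[v]] <- data.frame(level = rownames(counts),
                            n_0 = as.integer(counts[, "0"]),
                            pct_0 = as.numeric(pct[, "0"]),
                            n_1 = as.integer(counts[, "1"]),
                            pct_1 = as.numeric(pct[, "1"]),
                            row.names = NULL)
    observed <- droplevels(factor(x))
    if (nlevels(observed) < 2) {
      warning(sprintf("variable '%s' has a single observed level; test skipped",
                      v))
      tests[[v]] <- data.frame(variable = v, test = "skipped",
                               statistic = NA_real_, df = NA_real_,
                               p_value = NA_real_)
      next
    }
    if (is.ordered(x) || is.numeric(x)) {
      score <- if (is.numeric(x)) x else as.integer(x)
      tt <- stats::t.test(score ~ y)
      tests[[v]] <- data.frame(variable = v, test = "t",
                               statistic = unname(tt$statistic),
                               df = unname(tt$parameter),
                               p_value = tt$p.value)
    } else {
      ct <- suppressWarnings(
        stats::chisq.test(table(observed, y), correct = FALSE))
      tests[[v]] <- data.frame(variable = v, test = "chi-square",
                               statistic = unname(ct$statistic),
                               df = unname(ct$parameter),
                               p_value = ct$p.value)
    }
  }
  structure(list(tables = tabs, tests = do.call(rbind, c(tests,
                                                         make.row.names = FALSE))),
            class = "descriptive_report")
}

#' @export
print.descriptive_report <- function(x, ...) {
  cat("Descriptive comparison by outcome class\n")
  tst <- x$tests
  tst$statistic <- signif(tst$statistic, 4)
  tst$p_value <- signif(tst$p_value, 3)
  print(tst, row.names = FALSE)
  invisible(x)
}

#' Export a descriptive report as a delimited table
#'
#' One row per (variable, level) with counts/percentages by outcome class,
#' joined to the per-variable test results.
#'
#' @param report a `descriptive_report`.
#' @param path output CSV path.
#' @export
write_descriptive_report <- function(report, path) {
  rows <- lapply(names(report$tables), function(v) {
    cbind(variable = v, report$tables[[v]])
  })
  out <- do.call(rbind, rows)
  out <- merge(out, report$tests, by = "variable", sort = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
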