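#' Configure an end-to-end pipeline run
#'
#' Exactly one of `input` (a delimited episode file) or `generator` (a
#' [generator_config()]) must be supplied.
#'
#' @param input path to a CSV episode table, or `NULL`.
#' @param generator a [generator_config()], or `NULL`.
#' @param prep a [prep_config()].
#' @param spec the final Step-1 [classifier_spec()].
#' @param compare_specs optional list of specs for the repeated-split
#'   comparison stage (`NULL` skips the stage).
#' @param n_reps replicates for the comparison stage.
#' @param params Step-2 [tree_params()].
#' @param train_frac Step-1 training fraction.
#' @param alpha family-wise significance level for validation.
#' @param min_coverage minimum leaf coverage for subgroup selection.
#' @param correct continuity correction for validation tests.
#' @param seed master seed; every stage derives its own seed from it.
#' @param outdir output directory for the run artifacts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            prep = prep_config(),
                            spec = classifier_spec("random_forest"),
                            compare_specs = NULL, n_reps = 10,
                            params = tree_params(), train_frac = 0.2,
                            alpha = 0.05, min_coverage = 0.01,
                            correct = TRUE, seed = 1L, outdir = NULL) {
  if (is.null(input) == is.null(generator))
    vt_stop("exactly one of 'input' and 'generator' must be set",
            "vt_config_error")
  if (!is.null(generator) && !inherits(generator, "generator_config"))
    vt_stop("'generator' must be a generator_config", "vt_config_error")
  structure(list(input = input, generator = generator, prep = prep,
                 spec = spec, compare_specs = compare_specs,
                 n_reps = n_reps, params = params, train_frac = train_frac,
                 alpha = alpha, min_coverage = min_coverage,
                 correct = correct, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full subgroup-analysis pipeline
#'
#' Executes (optionally) simulate, prepare, compare-models, the virtual-twins
#' two-step run, and full-data subgroup validation, writing every artifact
#' and a run log into the output directory: `episodes.csv`,
#' `analytic.csv`, `descriptives.csv`, `comparison.csv` (if requested),
#' `vt_report.txt`, `tree.dot`, `validation.csv`, `run_log.txt`. All
#' randomness derives from the master seed via per-stage seed derivation, so
#' identical configurations produce identical outputs. On a stage failure a
#' `FAILED` marker naming the stage is left in the directory.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (defaults to `config$outdir`).
#' @return invisibly, a list with the analytic table, comparison report,
#'   `virtual_twins` fit and validation table.
#' @export
run_pipeline <- function(config, outdir = config$outdir) {
  if (!inherits(config, "pipeline_config"))
    vt_stop("'config' must be a pipeline_config", "vt_config_error")
  if (is.null(outdir)) vt_stop("an output directory is required",
                               "vt_config_error")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- "init"
  on_fail <- function(e) {
    writeLines(c(log_lines, paste("FAILED at stage:", stage),
                 conditionMessage(e)), log_path)
    writeLines(stage, file.path(outdir, "FAILED"))
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
      class = c("vt_pipeline_error", "vt_error", "error", "condition")))
  }
  result <- tryCatch({
    note("master seed: %d", config$seed)

    stage <- "simulate"
    if (!is.null(config$generator)) {
      sim_seed <- derive_seed(config$seed, "simulate")
      note("simulate: n = %d, seed = %d", config$generator$n_episodes,
           sim_seed)
      raw <- generate_episodes(config$generator, seed = sim_seed)
      if (config$generator$missing_rate > 0 ||
          config$generator$unknown_rate > 0) {
        raw <- inject_missing_and_unknowns(
          raw, config$generator$missing_rate, config$generator$unknown_rate,
          derive_seed(config$seed, "inject"))
      }
      write_generator_config(config$generator,
                             file.path(outdir, "generator_config.yaml"))
    } else {
      note("input: %s", config$input)
      raw <- read_episodes(config$input)
    }
    write_episodes(raw, file.path(outdir, "episodes.csv"))

    stage <- "prep"
    analytic <- prepare_analytic_table(raw, config$prep)
    dc <- attr(analytic, "drop_counts")
    note("prep: %s", paste(names(dc), dc, sep = "=", collapse = ", "))
    write_episodes(analytic, file.path(outdir, "analytic.csv"))
    desc <- descriptive_summary(analytic)
    write_descriptive_report(desc, file.path(outdir, "descriptives.csv"))

    stage <- "compare-models"
    comparison <- NULL
    if (!is.null(config$compare_specs)) {
      cmp_seed <- derive_seed(config$seed, "compare")
      note("compare-models: %d specs, %d reps, seed = %d",
           length(config$compare_specs), config$n_reps, cmp_seed)
      comparison <- compare_classifiers(
        analytic, config$compare_specs, n_reps = config$n_reps,
        train_frac = config$train_frac, seed = cmp_seed)
      write_comparison_report(comparison, file.path(outdir, "comparison.csv"))
    }

    stage <- "run-vt"
    vt_seed <- derive_seed(config$seed, "vt")
    note("run-vt: %s, train_frac = %g, seed = %d", config$spec$method,
         config$train_frac, vt_seed)
    fit <- virtual_twins(analytic, spec = config$spec,
                         params = config$params,
                         train_frac = config$train_frac,
                         min_coverage = config$min_coverage, seed = vt_seed)
    note("run-vt: %d leaves; selected: %s", length(fit$rules),
         format(fit$selected))
    write_vt_report(fit, file.path(outdir, "vt_report.txt"),
                    file.path(outdir, "tree.dot"))

    stage <- "validate"
    validation <- validate_subgroups(fit, analytic, alpha = config$alpha,
                                     correct = config$correct)
    note("validate: %d significant of %d rules; reversal = %s",
         sum(validation$significant & validation$rule != "marginal"),
         length(fit$rules), attr(validation, "reversal"))
    write_validation_table(validation, file.path(outdir, "validation.csv"))

    stage <- "finish"
    writeLines(log_lines, log_path)
    list(analytic = analytic, comparison = comparison, fit = fit,
         validation = validation, outdir = outdir)
  }, error = on_fail)
  invisible(result)
}
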