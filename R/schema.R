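#' Define a covariate schema for synthetic episode tables
#'
#' A schema lists the categorical/ordinal covariates of an episode table
#' together with their category labels and sampling probabilities. The names
#' `race` and `wait_binary` are reserved for the group attribute and the
#' outcome and cannot be used as covariate names.
#'
#' @param variables a list of variables created with [schema_variable()].
#' @return an object of class `teds_schema`.
#' @seealso [default_teds_schema()], [generator_config()]
#' @export
teds_schema <- function(variables) {
  if (!is.list(variables) || length(variables) == 0)
    vt_stop("'variables' must be a non-empty list of schema_variable()s",
            "vt_config_error")
  nm <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nm))
    vt_stop(sprintf("duplicate variable name '%s'", nm[duplicated(nm)][1]),
            "vt_config_error")
  reserved <- intersect(nm, c("race", "wait_binary"))
  if (length(reserved))
    vt_stop(sprintf("reserved name '%s' cannot be a covariate", reserved[1]),
            "vt_config_error")
  names(variables) <- nm
  structure(list(variables = variables), class = "teds_schema")
}

#' @rdname teds_schema
#' @param name variable name.
#' @param levels character vector of category labels (at least two).
#' @param probs sampling probabilities, one per level; must be non-negative
#'   and sum to 1. Defaults to uniform.
#' @param kind `"categorical"` (unordered) or `"ordinal"` (the level order is
#'   meaningful; ordinal variables are split by threshold in regression trees
#'   and scored by level index in descriptive t-tests).
#' @export
schema_variable <- function(name, levels, probs = NULL,
                            kind = c("categorical", "ordinal")) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    vt_stop("'name' must be a single non-empty string", "vt_config_error")
  if (length(levels) < 2)
    vt_stop(sprintf("variable '%s' needs >= 2 levels", name), "vt_config_error")
  if (anyDuplicated(levels))
    vt_stop(sprintf("variable '%s' has duplicated levels", name),
            "vt_config_error")
  probs <- probs %||% rep(1 / length(levels), length(levels))
  if (length(probs) != length(levels))
    vt_stop(sprintf("variable '%s': %d probs for %d levels", name,
                    length(probs), length(levels)), "vt_config_error")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    vt_stop(sprintf("variable '%s': probs must be non-negative and sum to 1",
                    name), "vt_config_error")
  list(name = name, kind = kind, levels = as.character(levels),
       probs = as.numeric(probs))
}

#' @export
print.teds_schema <- function(x, ...) {
  cat("Covariate schema:", length(x$variables), "variables\n")
  for (v in x$variables) {
    cat(sprintf("  %-18s %-11s %d levels: %s\n", v$name, v$kind,
                length(v$levels),
                paste(utils::head(v$levels, 6), collapse = ", ")))
  }
  invisible(x)
}

#' Default TEDS-like covariate schema
#'
#' Ten covariates emulating the admission-episode characteristics of a
#' national substance-use treatment registry: a many-level state indicator,
#' demographic bands, treatment-context variables, and an explicit
#' `"Unknown"` category for route of administration (unknown responses are a
#' regular category in such registries, distinct from missing cells). Level
#' probabilities are illustrative, not estimates of any real registry's
#' margins.
#'
#' @return a `teds_schema`.
#' @export
default_teds_schema <- function() {
  teds_schema(list(
    schema_variable("state",
      c("CA", "MD", "NY", "FL", "TX", "OH", "PA", "MI"),
      c(0.20, 0.18, 0.14, 0.12, 0.11, 0.10, 0.08, 0.07)),
    schema_variable("age_band",
      c("18-24", "25-34", "35-44", "45-54", "55+"),
      c(0.12, 0.36, 0.27, 0.16, 0.09), kind = "ordinal"),
    schema_variable("gender", c("Male", "Female"), c(0.66, 0.34)),
    schema_variable("education",
      c("Less than HS", "HS/GED", "Some college", "College+"),
      c(0.28, 0.42, 0.22, 0.08), kind = "ordinal"),
    schema_variable("employment",
      c("Full-time", "Part-time", "Unemployed", "Not in labor force"),
      c(0.17, 0.08, 0.45, 0.30)),
    schema_variable("homeless", c("No", "Yes"), c(0.82, 0.18)),
    schema_variable("referral_source",
      c("Self", "Provider", "Court/CJ", "Community"),
      c(0.55, 0.20, 0.15, 0.10)),
    schema_variable("mat", c("No", "Yes"), c(0.65, 0.35)),
    schema_variable("prior_episodes", c("0", "1", "2", "3+"),
      c(0.28, 0.25, 0.18, 0.29), kind = "ordinal"),
    schema_variable("route",
      c("Injection", "Smoking", "Oral/Inhalation", "Unknown"),
      c(0.48, 0.22, 0.27, 0.03))
  ))
}
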