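#' Describe a planted subgroup with an amplified group effect
#'
#' The synthetic outcome model is
#' \deqn{logit P(Y = 1 | D, X) = \beta_0 + \sum_j \beta_j(X_j)
#'       + (\delta_0 + \delta_S 1[X \in S]) D}
#' where `D` is the binary group attribute and `S` is the planted subgroup:
#' the set of covariate vectors satisfying every listed condition. Outside
#' `S` the group effect on the log-odds is `baseline_effect` (\eqn{\delta_0});
#' inside `S` it is `baseline_effect + subgroup_effect`
#' (\eqn{\delta_0 + \delta_S}). Because the group attribute enters only
#' through these two terms, the planted conjunction is the unique region of
#' elevated counterfactual difference, which makes subgroup recovery
#' unambiguous.
#'
#' @param conditions named list: for each condition variable, the character
#'   vector of levels that satisfy the condition. All conditions must hold
#'   for a row to be in the subgroup. An empty list plants no subgroup.
#' @param baseline_effect log-odds effect of `D = 1` outside the subgroup.
#' @param subgroup_effect additional log-odds effect of `D = 1` inside.
#' @return an object of class `planted_subgroup`.
#' @export
planted_subgroup <- function(conditions = list(), baseline_effect = 0,
                             subgroup_effect = 0) {
  if (length(conditions) && is.null(names(conditions)))
    vt_stop("'conditions' must be a named list (variable -> allowed levels)",
            "vt_config_error")
  structure(list(conditions = conditions,
                 baseline_effect = as.numeric(baseline_effect),
                 subgroup_effect = as.numeric(subgroup_effect)),
            class = "planted_subgroup")
}

#' Configure the synthetic episode generator
#'
#' @param schema a [teds_schema()].
#' @param n_episodes number of rows to generate.
#' @param race_prevalence probability that a row belongs to the focal group
#'   (`D = 1`, recorded as the second level of the `race` factor).
#' @param intercept model intercept \eqn{\beta_0} (log-odds).
#' @param beta named list of per-level log-odds effects: `beta$var` is a
#'   named numeric vector over (a subset of) that variable's levels;
#'   unlisted levels contribute 0.
#' @param planted a [planted_subgroup()].
#' @param missing_rate,unknown_rate default cell-corruption rates used by
#'   [inject_missing_and_unknowns()] when called through the pipeline.
#' @param seed default seed for [generate_episodes()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(schema, n_episodes, race_prevalence = 0.16,
                             intercept = 0, beta = list(),
                             planted = planted_subgroup(),
                             missing_rate = 0, unknown_rate = 0,
                             seed = NULL) {
  if (!inherits(schema, "teds_schema"))
    vt_stop("'schema' must be a teds_schema", "vt_config_error")
  if (!is.numeric(n_episodes) || n_episodes < 1)
    vt_stop("'n_episodes' must be >= 1", "vt_config_error")
  for (p in c(race_prevalence = race_prevalence, missing_rate = missing_rate,
              unknown_rate = unknown_rate)) {
    if (p < 0 || p > 1)
      vt_stop("rates/prevalences must lie in [0, 1]", "vt_config_error")
  }
  if (!inherits(planted, "planted_subgroup"))
    vt_stop("'planted' must be a planted_subgroup", "vt_config_error")
  vars <- schema$variables
  for (v in names(beta)) {
    if (!v %in% names(vars))
      vt_stop(sprintf("beta refers to unknown variable '%s'", v),
              "vt_config_error")
    bad <- setdiff(names(beta[[v]]), vars[[v]]$levels)
    if (length(bad))
      vt_stop(sprintf("beta['%s'] names unknown level '%s'", v, bad[1]),
              "vt_config_error")
  }
  for (v in names(planted$conditions)) {
    if (!v %in% names(vars))
      vt_stop(sprintf("planted condition on unknown variable '%s'", v),
              "vt_config_error")
    lev <- planted$conditions[[v]]
    if (length(lev) == 0 || !all(lev %in% vars[[v]]$levels) ||
        length(lev) >= length(vars[[v]]$levels))
      vt_stop(sprintf(
        "planted condition on '%s' must be a non-empty proper level subset",
        v), "vt_config_error")
  }
  structure(list(schema = schema, n_episodes = as.integer(n_episodes),
                 race_prevalence = race_prevalence, intercept = intercept,
                 beta = beta, planted = planted,
                 missing_rate = missing_rate, unknown_rate = unknown_rate,
                 seed = seed),
            class = "generator_config")
}

# linear predictor eta = beta0 + sum_j beta_j(x_j), without the group term
linear_predictor <- function(config, covariates) {
  eta <- rep(config$intercept, nrow(covariates))
  for (v in names(config$beta)) {
    x <- as.character(covariates[[v]])
    b <- config$beta[[v]]
    contrib <- b[x]
    contrib[is.na(contrib)] <- 0
    eta <- eta + contrib
  }
  eta
}

in_planted_subgroup <- function(planted, covariates) {
  ok <- rep(TRUE, nrow(covariates))
  for (v in names(planted$conditions)) {
    ok <- ok & (as.character(covariates[[v]]) %in% planted$conditions[[v]])
  }
  ok
}

check_covariates <- function(schema, covariates) {
  for (v in schema$variables) {
    if (!v$name %in% names(covariates))
      vt_stop(sprintf("covariate '%s' missing", v$name), "vt_schema_error")
    x <- as.character(covariates[[v$name]])
    if (anyNA(x))
      vt_stop(sprintf("covariate '%s' has missing values", v$name),
              "vt_schema_error")
    bad <- setdiff(unique(x), v$levels)
    if (length(bad))
      vt_stop(sprintf("covariate '%s' has unknown level '%s'", v$name, bad[1]),
              "vt_schema_error")
  }
  invisible(TRUE)
}

#' Generate a synthetic episode table
#'
#' Covariates are drawn independently per the schema's level probabilities,
#' the group indicator `D` is Bernoulli(`race_prevalence`), and the binary
#' outcome follows the logistic model documented in [planted_subgroup()].
#' No missingness is injected here; see [inject_missing_and_unknowns()].
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return a `data.frame` with columns `wait_binary` (integer 0/1), `race`
#'   (factor, levels `White` then `African American`), and one factor column
#'   per schema covariate (ordered factors for ordinal variables).
#' @export
generate_episodes <- function(config, seed = config$seed) {
  if (!inherits(config, "generator_config"))
    vt_stop("'config' must be a generator_config", "vt_config_error")
  if (is.null(seed))
    vt_stop("a seed is required (in the config or as an argument)",
            "vt_config_error")
  set.seed(seed)
  n <- config$n_episodes
  covs <- lapply(config$schema$variables, function(v) {
    x <- sample(v$levels, n, replace = TRUE, prob = v$probs)
    factor(x, levels = v$levels, ordered = v$kind == "ordinal")
  })
  covs <- as.data.frame(covs, stringsAsFactors = FALSE,
                        check.names = FALSE, optional = TRUE)
  names(covs) <- names(config$schema$variables)
  d <- stats::rbinom(n, 1, config$race_prevalence)
  eta <- linear_predictor(config, covs)
  delta <- config$planted$baseline_effect +
    config$planted$subgroup_effect * in_planted_subgroup(config$planted, covs)
  y <- stats::rbinom(n, 1, stats::plogis(eta + delta * d))
  out <- cbind(
    data.frame(
      wait_binary = y,
      race = factor(ifelse(d == 1, "African American", "White"),
                    levels = c("White", "African American"))),
    covs)
  rownames(out) <- NULL
  out
}

#' Exact counterfactual probability difference under the generating model
#'
#' For covariate vector(s) `X`, returns the model's true per-record virtual
#' difference
#' \deqn{Z(X) = expit(\eta + \delta_0 + \delta_S 1[X \in S]) - expit(\eta)},
#' \eqn{\eta = \beta_0 + \sum_j \beta_j(X_j)}: the extra probability of the
#' adverse outcome attributable solely to `D = 1` at those covariates. Exact
#' (no sampling); used as the oracle against which fitted virtual
#' differences are judged.
#'
#' @param config a [generator_config()].
#' @param covariates a `data.frame` (or single-row list) of complete
#'   covariate values with the schema's variables.
#' @return numeric vector in `[-1, 1]`, one value per row.
#' @export
true_virtual_difference <- function(config, covariates) {
  if (!inherits(config, "generator_config"))
    vt_stop("'config' must be a generator_config", "vt_config_error")
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  check_covariates(config$schema, covariates)
  eta <- linear_predictor(config, covariates)
  delta <- config$planted$baseline_effect +
    config$planted$subgroup_effect *
      in_planted_subgroup(config$planted, covariates)
  stats::plogis(eta + delta) - stats::plogis(eta)
}

#' Inject missing cells and explicit "Unknown" responses
#'
#' Each covariate cell is independently replaced by `NA` with probability
#' `missing_rate`, or by the variable's `"Unknown"` level with probability
#' `unknown_rate` (the level is appended to the factor if absent). The
#' outcome and group columns are never altered. Unknown responses model
#' recorded non-answers (an ordinary analysis category); missing cells model
#' unrecorded values, which the preparation step deletes row-wise.
#'
#' @param table an episode `data.frame` from [generate_episodes()].
#' @param missing_rate,unknown_rate per-cell probabilities in `[0, 1]`.
#' @param seed integer seed.
#' @return the corrupted episode table.
#' @export
inject_missing_and_unknowns <- function(table, missing_rate, unknown_rate,
                                        seed) {
  if (missing_rate < 0 || missing_rate > 1 || unknown_rate < 0 ||
      unknown_rate > 1 || missing_rate + unknown_rate > 1)
    vt_stop("rates must lie in [0, 1] and sum to at most 1",
            "vt_config_error")
  if (missing_rate == 0 && unknown_rate == 0) return(table)
  set.seed(seed)
  covnames <- setdiff(names(table), c("wait_binary", "race"))
  for (v in covnames) {
    u <- stats::runif(nrow(table))
    miss <- u < missing_rate
    unk <- !miss & u < missing_rate + unknown_rate
    x <- table[[v]]
    if (any(unk)) {
      if (!"Unknown" %in% levels(x)) levels(x) <- c(levels(x), "Unknown")
      x[unk] <- "Unknown"
    }
    x[miss] <- NA
    table[[v]] <- x
  }
  table
}

#' Calibrate the generator intercept to a target outcome prevalence
#'
#' Solves for the intercept \eqn{\beta_0} such that the marginal outcome
#' probability `E[P(Y = 1 | D, X)]` under the configured covariate and group
#' distributions equals `target`. The expectation is evaluated on one large
#' fixed covariate draw, so the result is deterministic given `seed`.
#'
#' @param config a [generator_config()]; its `intercept` is ignored.
#' @param target desired marginal prevalence of `Y = 1`.
#' @param n Monte Carlo draw size for the expectation.
#' @param seed seed for the evaluation draw.
#' @return the calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(config, target, n = 200000, seed = 1L) {
  set.seed(seed)
  covs <- lapply(config$schema$variables, function(v) {
    factor(sample(v$levels, n, replace = TRUE, prob = v$probs),
           levels = v$levels, ordered = v$kind == "ordinal")
  })
  covs <- as.data.frame(covs, check.names = FALSE, optional = TRUE)
  names(covs) <- names(config$schema$variables)
  d <- stats::rbinom(n, 1, config$race_prevalence)
  cfg0 <- config
  cfg0$intercept <- 0
  eta0 <- linear_predictor(cfg0, covs)
  delta <- config$planted$baseline_effect +
    config$planted$subgroup_effect * in_planted_subgroup(config$planted, covs)
  f <- function(b0) mean(stats::plogis(b0 + eta0 + delta * d)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

#' Default calibrated generator configuration
#'
#' The package's reference synthetic-study conditions: the
#' [default_teds_schema()] covariates, focal-group prevalence 0.16, modest
#' covariate effects, and a planted two-condition subgroup
#' (`state` in \{CA, MD\} and `mat` = "Yes", about 13% of episodes) in which
#' the group effect on the wait log-odds rises from \eqn{\delta_0 = -0.3}
#' outside to \eqn{\delta_0 + \delta_S = +0.3} inside. This reproduces the
#' qualitative structure of the motivating disparity analysis: a marginal
#' association slightly *favoring* the focal group (marginal mean Z below 0)
#' that reverses sign inside the planted subgroup, where the true
#' counterfactual difference is about +0.06. The intercept was set with
#' [calibrate_intercept()] so the marginal wait prevalence is 0.302.
#'
#' @param n_episodes rows to generate (default 50,000).
#' @param seed default generation seed stored in the config.
#' @param baseline_effect,subgroup_effect group log-odds effects outside the
#'   planted subgroup and the increment inside it.
#' @return a `generator_config`.
#' @export
default_generator_config <- function(n_episodes = 50000, seed = NULL,
                                     baseline_effect = -0.3,
                                     subgroup_effect = 0.6) {
  schema <- default_teds_schema()
  beta <- list(
    state = c(CA = 0.10, MD = -0.10, NY = 0.05, TX = 0.05, OH = -0.05,
              MI = 0.02),
    age_band = c("25-34" = 0.05, "35-44" = 0.10, "45-54" = 0.15,
                 "55+" = 0.20),
    gender = c(Female = 0.05),
    education = c("HS/GED" = -0.05, "Some college" = -0.10,
                  "College+" = -0.15),
    employment = c("Part-time" = 0.05, Unemployed = 0.25,
                   "Not in labor force" = 0.15),
    homeless = c(Yes = 0.35),
    referral_source = c(Provider = -0.15, "Court/CJ" = 0.20,
                        Community = 0.10),
    mat = c(Yes = -0.10),
    prior_episodes = c("1" = 0.10, "2" = 0.15, "3+" = 0.20),
    route = c(Injection = 0.20, Smoking = 0.10, Unknown = 0.05)
  )
  planted <- planted_subgroup(
    conditions = list(state = c("CA", "MD"), mat = "Yes"),
    baseline_effect = baseline_effect,
    subgroup_effect = subgroup_effect)
  generator_config(
    schema = schema, n_episodes = n_episodes, race_prevalence = 0.16,
    intercept = -1.30619, # calibrate_intercept(., target = 0.302)
    beta = beta, planted = planted, seed = seed)
}

#' Generator configuration for subgroup-recovery studies
#'
#' A controlled variant of [default_generator_config()] for experiments that
#' ask whether the two-step pipeline can rediscover a known planted
#' subgroup. Against the realism-oriented default it makes three changes,
#' each moving toward a clean step-shaped Z surface in which the planted
#' conjunction is the only structure there is to find:
#' covariate main effects are removed (the ten covariates are pure noise
#' outside the planted rule), the baseline log-odds are lowered (intercept
#' -2.5) so the group effect outside the subgroup translates into a
#' near-zero probability difference (a flat -0.019), and the subgroup
#' increment is solved in closed form so the true counterfactual
#' difference inside the planted cell (`state` in \{CA, MD\} and
#' `mat` = "Yes") is exactly 0.060 (\eqn{\delta_0 = -0.3},
#' \eqn{\delta_S = 0.94987}). The focal-group share is 0.34, the share
#' observed in the Maryland subgroup of the motivating analysis; recovery
#' of a group-by-covariate interaction is information-limited by the
#' focal-group episode count inside the planted cell, and at shares far
#' below this the Step-1 training data simply do not contain enough
#' focal-group outcome events for any classifier to resolve the cell.
#'
#' @param n_episodes rows to generate (default 50,000).
#' @param seed default generation seed stored in the config.
#' @return a `generator_config`.
#' @export
recovery_generator_config <- function(n_episodes = 50000, seed = NULL) {
  schema <- default_teds_schema()
  # deltaS solving expit(-2.5 - 0.3 + dS) = expit(-2.5) + 0.06 exactly
  b0 <- -2.5
  dS <- stats::qlogis(stats::plogis(b0) + 0.06) - b0 + 0.3
  generator_config(
    schema = schema, n_episodes = n_episodes, race_prevalence = 0.34,
    intercept = b0, beta = list(),
    planted = planted_subgroup(
      conditions = list(state = c("CA", "MD"), mat = "Yes"),
      baseline_effect = -0.3, subgroup_effect = dS),
    seed = seed)
}

#' Read or write episode tables as delimited text
#'
#' Comma-separated, header row, missing cells as empty fields. `read_episodes`
#' restores factor dictionaries from a schema when given one (recommended, so
#' that rarely observed levels are not dropped from the dictionary).
#'
#' @param table episode `data.frame`.
#' @param path file path.
#' @param schema optional [teds_schema()] used to re-establish factor levels.
#' @return `read_episodes` returns the episode `data.frame`.
#' @export
write_episodes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path, schema = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, na.strings = "")
  if ("race" %in% names(tab))
    tab$race <- factor(tab$race, levels = c("White", "African American"))
  for (v in setdiff(names(tab), c("wait_binary", "race"))) {
    if (!is.null(schema) && v %in% names(schema$variables)) {
      sv <- schema$variables[[v]]
      lev <- union(sv$levels, setdiff(unique(stats::na.omit(tab[[v]])),
                                      sv$levels))
      tab[[v]] <- factor(tab[[v]], levels = lev,
                         ordered = sv$kind == "ordinal")
    } else if (is.character(tab[[v]])) {
      tab[[v]] <- factor(tab[[v]])
    }
  }
  tab
}

#' Serialize a generator configuration to a YAML text file
#'
#' @param config a [generator_config()].
#' @param path file path.
#' @export
write_generator_config <- function(config, path) {
  x <- list(
    n_episodes = config$n_episodes,
    race_prevalence = config$race_prevalence,
    intercept = config$intercept,
    seed = config$seed,
    missing_rate = config$missing_rate,
    unknown_rate = config$unknown_rate,
    beta = lapply(config$beta, as.list),
    planted = list(conditions = lapply(config$planted$conditions, as.list),
                   baseline_effect = config$planted$baseline_effect,
                   subgroup_effect = config$planted$subgroup_effect),
    schema = lapply(config$schema$variables, function(v)
      list(kind = v$kind, levels = as.list(v$levels),
           probs = as.list(v$probs)))
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_generator_config
#' @return `read_generator_config` returns the restored `generator_config`.
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  schema <- teds_schema(lapply(names(x$schema), function(nm) {
    v <- x$schema[[nm]]
    schema_variable(nm, unlist(v$levels), unlist(v$probs), v$kind)
  }))
  planted <- planted_subgroup(
    conditions = lapply(x$planted$conditions, unlist),
    baseline_effect = x$planted$baseline_effect,
    subgroup_effect = x$planted$subgroup_effect)
  generator_config(
    schema = schema, n_episodes = x$n_episodes,
    race_prevalence = x$race_prevalence, intercept = x$intercept,
    beta = lapply(x$beta, unlist), planted = planted,
    missing_rate = x$missing_rate %||% 0, unknown_rate = x$unknown_rate %||% 0,
    seed = x$seed)
}
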