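# Shared fixtures and independent oracles, built in code at test time.

# small two-binary-covariate schema for analytic checks
tiny_schema <- function() {
  teds_schema(list(
    schema_variable("a", c("a1", "a2"), c(0.5, 0.5)),
    schema_variable("b", c("b1", "b2"), c(0.5, 0.5))
  ))
}

tiny_config <- function(n = 1000, intercept = 0, beta = list(),
                        planted = planted_subgroup(), race_prevalence = 0.5,
                        seed = 1L) {
  generator_config(tiny_schema(), n, race_prevalence = race_prevalence,
                   intercept = intercept, beta = beta, planted = planted,
                   seed = seed)
}

# three-binary-covariate schema for exhaustive enumeration oracles
three_bin_schema <- function() {
  teds_schema(list(
    schema_variable("a", c("a1", "a2"), c(0.3, 0.7)),
    schema_variable("b", c("b1", "b2"), c(0.6, 0.4)),
    schema_variable("c", c("c1", "c2"), c(0.5, 0.5))
  ))
}

# brute-force best single split over every admissible condition of every
# covariate: all 2^(L-1)-1 bipartitions for categorical, all thresholds for
# ordinal/numeric. Returns the maximal SSE reduction (and one argmax).
exhaustive_best_split <- function(X, z, min_leaf = 1) {
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  parent <- sse(z)
  best <- list(gain = -Inf, variable = NULL, levels = NULL, threshold = NULL)
  for (v in names(X)) {
    x <- X[[v]]
    if (is.numeric(x) || is.ordered(x)) {
      xo <- if (is.numeric(x)) x else as.integer(x)
      for (thr in sort(unique(xo))[-length(unique(xo))]) {
        left <- xo <= thr
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        gain <- parent - sse(z[left]) - sse(z[!left])
        if (gain > best$gain)
          best <- list(gain = gain, variable = v, threshold = thr,
                       levels = NULL)
      }
    } else {
      lev <- unique(as.character(x))
      if (length(lev) < 2) next
      for (mask in 1:(2^(length(lev) - 1) - 1)) {
        subset <- lev[bitwAnd(mask, 2^(seq_along(lev) - 1)) > 0]
        left <- as.character(x) %in% subset
        if (sum(left) < min_leaf || sum(!left) < min_leaf) next
        gain <- parent - sse(z[left]) - sse(z[!left])
        if (gain > best$gain)
          best <- list(gain = gain, variable = v, levels = subset,
                       threshold = NULL)
      }
    }
  }
  if (!is.finite(best$gain)) NULL else best
}

# random small table of categorical/ordinal covariates with numeric z
random_tree_instance <- function(n, n_levels = 4, seed) {
  set.seed(seed)
  X <- data.frame(
    u = factor(sample(letters[1:n_levels], n, replace = TRUE)),
    v = factor(sample(LETTERS[1:3], n, replace = TRUE)),
    w = factor(sample(c("lo", "mid", "hi"), n, replace = TRUE),
               levels = c("lo", "mid", "hi"), ordered = TRUE))
  z <- stats::rnorm(n)
  list(X = X, z = z)
}

# register a deterministic lookup-table stub classifier:
# returns p1 when D = 1 and p0 when D = 0, ignoring covariates
register_lookup_stub <- function(p1 = 0.6, p0 = 0.4) {
  register_classifier("lookup_stub",
    fit = function(x, y, params, seed) list(p1 = p1, p0 = p0),
    predict = function(fit, x) ifelse(x[, "D"] == 1, fit$p1, fit$p0))
  classifier_spec("lookup_stub")
}

# stub whose probabilities depend on covariates but never on D (race-blind)
register_raceblind_stub <- function() {
  register_classifier("raceblind_stub",
    fit = function(x, y, params, seed) NULL,
    predict = function(fit, x) {
      cols <- setdiff(colnames(x), "D")
      stats::plogis(as.numeric(x[, cols] %*% seq_along(cols)) / 50 - 1)
    })
  classifier_spec("raceblind_stub")
}
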