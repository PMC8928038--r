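`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vt_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "vt_error", "error", "condition")))
}

#' Derive a per-stage seed from a master seed
#'
#' Hashes a stage label into the master seed so that every random decision in
#' a pipeline run has its own reproducible stream, decoupled from edits to
#' other stages. The result is always a valid 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- abs(as.double(master)) %% 2147483647
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Mann-Whitney AUC from scores and 0/1 labels; ties get average rank.
rank_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# identify the focal (D = 1) level of a two-level group factor:
# by convention the second factor level (reference level first).
group_indicator <- function(x, var = "race") {
  if (!is.factor(x)) x <- factor(x)
  if (nlevels(x) != 2L) {
    vt_stop(sprintf("group variable '%s' must have exactly 2 levels, got %d",
                    var, nlevels(x)), "vt_schema_error")
  }
  as.integer(x == levels(x)[2L])
}
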