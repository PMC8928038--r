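test_that("schema and config validation reject malformed inputs", {
  expect_error(schema_variable("x", "one_level"), class = "vt_config_error")
  expect_error(schema_variable("x", c("a", "b"), c(0.6, 0.6)),
               class = "vt_config_error")
  expect_error(teds_schema(list(schema_variable("race", c("a", "b")))),
               class = "vt_config_error")
  expect_error(
    generator_config(tiny_schema(), 0),
    class = "vt_config_error")
  expect_error(
    generator_config(tiny_schema(), 10, beta = list(zzz = c(a1 = 1))),
    class = "vt_config_error")
  expect_error(
    generator_config(tiny_schema(), 10,
                     planted = planted_subgroup(list(a = c("a1", "a2")))),
    class = "vt_config_error")
})

test_that("generation is deterministic and respects the schema", {
  cfg <- tiny_config(n = 500, seed = 11)
  t1 <- generate_episodes(cfg)
  t2 <- generate_episodes(cfg)
  expect_identical(t1, t2)
  t3 <- generate_episodes(cfg, seed = 12)
  expect_false(identical(t1, t3))
  expect_setequal(names(t1), c("wait_binary", "race", "a", "b"))
  expect_true(all(t1$wait_binary %in% 0:1))
  expect_identical(levels(t1$race), c("White", "African American"))
  expect_true(all(levels(t1$a) == c("a1", "a2")))
})

test_that("race-blind symmetric model gives equal wait rates near 0.5", {
  cfg <- tiny_config(n = 40000, intercept = 0, seed = 3)
  tab <- generate_episodes(cfg)
  d <- as.integer(tab$race == "African American")
  r1 <- mean(tab$wait_binary[d == 1])
  r0 <- mean(tab$wait_binary[d == 0])
  expect_lt(abs(r1 - 0.5), 0.02)
  expect_lt(abs(r0 - 0.5), 0.02)
  expect_lt(abs(r1 - r0), 0.03)
})

test_that("planted-cell wait-rate gap matches closed-form cell probabilities", {
  # logistic model with beta0 = -2, delta0 = -0.3, deltaS = +1.2 on a
  # two-binary-covariate planted cell; the empirical AA-White gap inside the
  # cell must match expit(beta0 + delta0 + deltaS) - expit(beta0) within
  # 3 Monte-Carlo standard errors
  n <- 50000
  cfg <- tiny_config(
    n = n, intercept = -2,
    planted = planted_subgroup(list(a = "a1", b = "b1"),
                               baseline_effect = -0.3,
                               subgroup_effect = 1.2),
    seed = 21)
  tab <- generate_episodes(cfg)
  inside <- tab$a == "a1" & tab$b == "b1"
  d <- as.integer(tab$race == "African American")
  p_aa <- plogis(-2 - 0.3 + 1.2)
  p_w <- plogis(-2)
  k1 <- sum(inside & d == 1)
  k0 <- sum(inside & d == 0)
  gap_hat <- mean(tab$wait_binary[inside & d == 1]) -
    mean(tab$wait_binary[inside & d == 0])
  se <- sqrt(p_aa * (1 - p_aa) / k1 + p_w * (1 - p_w) / k0)
  expect_lt(abs(gap_hat - (p_aa - p_w)), 3 * se)
})

test_that("true_virtual_difference matches analytic logistic arithmetic", {
  # no race effect -> 0 everywhere
  cfg0 <- tiny_config(n = 10)
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  expect_equal(true_virtual_difference(cfg0, grid), rep(0, 4))

  # eta = 0, delta0 = 0, deltaS = ln 3 inside the subgroup:
  # expit(ln 3) - expit(0) = 0.75 - 0.5 = 0.25
  cfg1 <- tiny_config(
    n = 10, intercept = 0,
    planted = planted_subgroup(list(a = "a1"), 0, log(3)))
  z <- true_virtual_difference(cfg1, grid)
  expect_equal(z[grid$a == "a1"], rep(0.25, 2))
  expect_equal(z[grid$a == "a2"], rep(0, 2))

  expect_error(true_virtual_difference(cfg1, data.frame(a = "zz", b = "b1")),
               class = "vt_schema_error")
})

test_that("population mean of Z from full enumeration matches brute-force probability summation", {
  cfg <- generator_config(
    three_bin_schema(), 10, race_prevalence = 0.4, intercept = -0.5,
    beta = list(a = c(a2 = 0.8), b = c(b2 = -0.4), c = c(c2 = 0.3)),
    planted = planted_subgroup(list(a = "a2", c = "c1"), -0.2, 0.9))
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                      c = c("c1", "c2"), stringsAsFactors = FALSE)
  # independent oracle: direct probability summation over the 8 cells
  pa <- c(a1 = 0.3, a2 = 0.7); pb <- c(b1 = 0.6, b2 = 0.4)
  pc <- c(c1 = 0.5, c2 = 0.5)
  w <- pa[grid$a] * pb[grid$b] * pc[grid$c]
  eta <- -0.5 + 0.8 * (grid$a == "a2") - 0.4 * (grid$b == "b2") +
    0.3 * (grid$c == "c2")
  inS <- grid$a == "a2" & grid$c == "c1"
  z_oracle <- plogis(eta - 0.2 + 0.9 * inS) - plogis(eta)
  expect_equal(sum(w * true_virtual_difference(cfg, grid)),
               sum(w * z_oracle), tolerance = 1e-12)
})

test_that("Z is bounded, zero iff no race effect, and monotone in the subgroup effect", {
  grid <- expand.grid(a = c("a1", "a2"), b = c("b1", "b2"),
                      stringsAsFactors = FALSE)
  for (seed in 1:20) {
    set.seed(seed)
    cfg <- tiny_config(
      n = 10, intercept = rnorm(1),
      beta = list(a = c(a2 = rnorm(1))),
      planted = planted_subgroup(list(b = "b1"), rnorm(1), rnorm(1)))
    z <- true_virtual_difference(cfg, grid)
    expect_true(all(z >= -1 & z <= 1))
    # strictly increasing in deltaS inside the planted cell, constant outside
    cfg2 <- cfg
    cfg2$planted$subgroup_effect <- cfg$planted$subgroup_effect + 0.5
    z2 <- true_virtual_difference(cfg2, grid)
    expect_true(all(z2[grid$b == "b1"] > z[grid$b == "b1"]))
    expect_equal(z2[grid$b == "b2"], z[grid$b == "b2"])
  }
})

test_that("missing/unknown injection hits the configured rates and never touches outcome or group", {
  cfg <- tiny_config(n = 10000, seed = 5)
  tab <- generate_episodes(cfg)
  expect_identical(inject_missing_and_unknowns(tab, 0, 0, seed = 1), tab)

  all_na <- inject_missing_and_unknowns(tab, 1, 0, seed = 1)
  expect_true(all(is.na(all_na$a)) && all(is.na(all_na$b)))
  expect_identical(all_na$wait_binary, tab$wait_binary)
  expect_identical(all_na$race, tab$race)

  ten <- inject_missing_and_unknowns(tab, 0.1, 0.05, seed = 2)
  frac_missing <- mean(is.na(ten$a) | FALSE) / 2 + mean(is.na(ten$b)) / 2
  expect_gt(frac_missing, 0.09)
  expect_lt(frac_missing, 0.11)
  frac_unknown <- mean(ten$a == "Unknown", na.rm = TRUE)
  expect_gt(frac_unknown, 0.04)
  expect_lt(frac_unknown, 0.065)
  expect_error(inject_missing_and_unknowns(tab, 1.2, 0, 1),
               class = "vt_config_error")
})

test_that("episode tables and generator configs round-trip through text files", {
  cfg <- default_generator_config(n_episodes = 200, seed = 8)
  tab <- generate_episodes(cfg)
  tab <- inject_missing_and_unknowns(tab, 0.05, 0.02, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_episodes(tab, f)
  back <- read_episodes(f, schema = cfg$schema)
  expect_equal(back$wait_binary, tab$wait_binary)
  expect_equal(as.character(back$race), as.character(tab$race))
  for (v in names(cfg$schema$variables))
    expect_equal(as.character(back[[v]]), as.character(tab[[v]]))

  fy <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, fy)
  cfg2 <- read_generator_config(fy)
  expect_equal(cfg2$intercept, cfg$intercept)
  expect_equal(cfg2$beta, cfg$beta)
  expect_equal(cfg2$planted$conditions, cfg$planted$conditions)
  expect_identical(generate_episodes(cfg2, seed = 8),
                   generate_episodes(cfg, seed = 8))
})
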