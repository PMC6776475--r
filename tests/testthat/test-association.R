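test_that("crude odds ratio and Wald CI match the cross-product formula", {
  r <- crude_or_ci(n_ref = 44, x_ref = 3, n_cmp = 173, x_cmp = 39)
  expect_equal(r$or, 39 * 41 / (134 * 3))
  expect_equal(r$or, 3.977612, tolerance = 1e-6)
  expect_equal(r$ci_low, 1.168110, tolerance = 1e-6)
  expect_equal(r$ci_high, 13.544442, tolerance = 1e-6)

  r2 <- crude_or_ci(n_ref = 52, x_ref = 15, n_cmp = 280, x_cmp = 57)
  expect_equal(round(r2$or, 2), 0.63)

  same <- crude_or_ci(100, 20, 100, 20)
  expect_equal(same$or, 1)

  sep <- crude_or_ci(n_ref = 10, x_ref = 2, n_cmp = 8, x_cmp = 0)
  expect_false(sep$defined)
  expect_true(is.na(sep$or))
  corr <- crude_or_ci(10, 2, 8, 0, continuity_correction = TRUE)
  expect_true(corr$defined)
  expect_equal(corr$or, (0.5 * 8.5) / (8.5 * 2.5))
})

test_that("scaling all cell counts leaves the OR fixed and narrows the CI", {
  base <- crude_or_ci(50, 10, 60, 25)
  for (k in c(2, 5, 10)) {
    sc <- crude_or_ci(50 * k, 10 * k, 60 * k, 25 * k)
    expect_equal(sc$or, base$or)
    expect_lt(sc$ci_high - sc$ci_low, base$ci_high - base$ci_low)
    base <- sc
  }
})

test_that("two-sample t-test matches the textbook pooled formula", {
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.6742346, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.0213116, tolerance = 1e-5)

  sw <- two_sample_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(sw$t, -tt$t)
  expect_equal(sw$p_value, tt$p_value)

  eq <- two_sample_t(c(1, 2, 4), c(1, 2, 4))
  expect_equal(eq$t, 0)
  expect_equal(eq$p_value, 1)

  expect_warning(dg <- two_sample_t(c(2, 2, 2), c(2, 2)), "undefined")
  expect_true(is.na(dg$p_value))
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("saturated one-covariate logistic fit equals the closed-form OR", {
  # counts: ref 44 total / 3 cases, cmp 173 total / 39 cases
  x <- factor(rep(c("ref", "cmp"), c(44, 173)), levels = c("ref", "cmp"))
  y <- c(rep(c(1, 0), c(3, 41)), rep(c(1, 0), c(39, 134)))
  fit <- fit_excessive_model(data.frame(g = x), y)
  est <- fit$estimates[fit$estimates$category == "cmp", ]
  closed <- crude_or_ci(44, 3, 173, 39)
  expect_equal(est$or, closed$or, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$gradient_norm, 1e-8)
})

test_that("null outcome model yields odds ratios near one at large n", {
  cfg <- sim_config(n_children = 6000, log_or = "null")
  cohort <- gen_cohort(cfg, seed = 31)
  covs <- derive_covariates(cohort$raw)
  fit <- fit_excessive_model(covs, cohort$truth$excessive)
  est <- fit$estimates
  est <- est[!est$reference & est$defined, ]
  expect_true(all(abs(est$log_or) < 3.9 * est$se))
})

test_that("constant covariates are dropped with a warning", {
  d <- data.frame(a = factor(rep(c("x", "y"), 25)),
                  b = factor(rep("only", 50)))
  y <- rep(c(0, 1), 25)
  expect_warning(fit <- fit_excessive_model(d, y), "constant")
  expect_false("b" %in% fit$estimates$variable)
})

test_that("perfect separation is flagged undefined, not reported as a number", {
  d <- data.frame(g = factor(rep(c("r", "s", "t"), c(40, 40, 6)),
                             levels = c("r", "s", "t")))
  y <- c(rbinom(40, 1, 0.3), rbinom(40, 1, 0.4), rep(0, 6))
  tab <- association_table(d, y)
  row_t <- tab[tab$category == "t", ]
  expect_false(row_t$crude_defined)
  expect_false(row_t$adj_defined)
  fmt <- format_association_table(tab)
  expect_equal(fmt$crude[fmt$category == "t"], "-")
})

test_that("association table counts and reference rows are correct", {
  set.seed(41)
  d <- data.frame(g = factor(sample(c("a", "b"), 80, TRUE), levels = c("a", "b")))
  y <- rbinom(80, 1, 0.3)
  tab <- association_table(d, y)
  expect_equal(sum(tab$n_total), 80)
  expect_equal(sum(tab$n_excessive), sum(y))
  expect_equal(tab$crude_or[tab$reference], 1)
  expect_equal(tab$adj_or[tab$reference], 1)
  # single covariate: adjusted equals crude
  cmp <- tab[!tab$reference, ]
  expect_equal(cmp$adj_or, cmp$crude_or, tolerance = 1e-6)
})
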