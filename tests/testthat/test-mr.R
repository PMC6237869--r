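caffeine_ins <- bitter_instruments()[3L, ]
prop_ins <- bitter_instruments()[1L, ]

test_that("wald ratio reproduces hand-computed values", {
  a <- association_result("rs2597979", "coffee_cups", beta = 0.039,
                          se = se_from_ci(0.027, 0.050), n = 438870,
                          model = "linear")
  w <- wald_ratio(a, caffeine_ins, se_mode = "first_order")
  expect_equal(w$estimate, 0.039 / 0.264, tolerance = 1e-12)
  expect_equal(w$se, se_from_ci(0.027, 0.050) / 0.264, tolerance = 1e-12)
  expect_identical(w$scale, "linear")

  null <- wald_ratio(list(beta = 0, se = 0.01, model = "linear",
                          phenotype = "coffee_cups", n = 1000L), caffeine_ins)
  expect_identical(null$estimate, 0)
  expect_identical(null$p, 1)

  bad <- caffeine_ins
  bad$beta_bitter <- 0
  expect_error(wald_ratio(a, bad), "undefined")
  expect_error(wald_ratio(association_result("x", "s", 0.1, 0.05, 500, "logistic"),
                          caffeine_ins),
               "linear")
})

test_that("delta-method modes behave as documented", {
  a <- list(beta = 0.039, se = 0.006, model = "linear", phenotype = "c", n = 1000L)
  w1 <- wald_ratio(a, caffeine_ins, "first_order")
  w2 <- wald_ratio(a, caffeine_ins, "full_delta")
  expect_gt(w2$se, w1$se)  # instrument uncertainty inflates the SE
  expect_equal(w2$se,
               sqrt(0.006^2 / 0.264^2 + 0.039^2 * caffeine_ins$se_bitter^2 / 0.264^4),
               tolerance = 1e-12)
  # modes converge as the instrument SE vanishes
  precise <- caffeine_ins
  precise$se_bitter <- 1e-9
  w3 <- wald_ratio(a, precise, "full_delta")
  expect_equal(w3$se, w1$se, tolerance = 1e-8)
})

test_that("full-delta SE matches the Monte-Carlo SD of the ratio for strong instruments", {
  set.seed(61)
  n_rep <- 10000L
  b_bev <- 0.039; se_bev <- 0.0059
  b_bit <- prop_ins$beta_bitter; se_bit <- prop_ins$se_bitter  # z = 30
  num <- rnorm(n_rep, b_bev, se_bev)
  den <- rnorm(n_rep, b_bit, se_bit)
  mc_sd <- sd(num / den)
  delta <- wald_ratio(list(beta = b_bev, se = se_bev, model = "linear",
                           phenotype = "c", n = 1000L), prop_ins, "full_delta")$se
  expect_lt(abs(delta - mc_sd) / mc_sd, 0.05)
})

test_that("wald ratio is scale-equivariant in the outcome", {
  a <- list(beta = 0.04, se = 0.006, model = "linear", phenotype = "c", n = 1000L)
  w <- wald_ratio(a, caffeine_ins)
  a10 <- list(beta = 0.4, se = 0.06, model = "linear", phenotype = "c", n = 1000L)
  w10 <- wald_ratio(a10, caffeine_ins)
  expect_equal(w10$estimate, 10 * w$estimate, tolerance = 1e-12)
  expect_equal(w10$se, 10 * w$se, tolerance = 1e-12)
})

test_that("causal OR is the exponentiated log-scale wald ratio", {
  log_or <- log(1.207) * 0.264
  a <- association_result("rs2597979", "coffee_status", beta = log_or,
                          se = 0.01, n = 30000L, model = "logistic")
  or <- causal_or(a, caffeine_ins, "first_order")
  expect_equal(or$estimate, 1.207, tolerance = 1e-9)
  expect_identical(or$scale, "odds_ratio")
  expect_true(or$ci_low < or$estimate && or$estimate < or$ci_high)

  lin <- wald_ratio(list(beta = log_or, se = 0.01, model = "linear",
                         phenotype = "log odds", n = 30000L),
                    caffeine_ins, "first_order")
  expect_equal(or$estimate, exp(lin$estimate), tolerance = 1e-12)
  expect_equal(or$ci_low, exp(lin$ci_low), tolerance = 1e-12)

  null <- causal_or(list(beta = 0, se = 0.01, model = "logistic",
                         phenotype = "s", n = 1000L), caffeine_ins)
  expect_identical(null$estimate, 1)

  expect_error(causal_or(list(beta = 0.1, se = 0.05, model = "linear",
                              phenotype = "s", n = 500L), caffeine_ins),
               "logistic")
})

test_that("instrument F follows the one-regressor convention", {
  expect_identical(instrument_f(0, 10), 0)
  expect_equal(instrument_f(0.5, 4), 2)
  # inversion: the R2 at which F = 10 for n = 1757
  r2_weak <- 10 / (1757 - 2 + 10)
  expect_equal(instrument_f(r2_weak, 1757), 10, tolerance = 1e-12)
  expect_equal(r2_weak, 0.00567, tolerance = 1e-3)
  expect_error(instrument_f(1.2, 100), "variance_explained")
  expect_error(instrument_f(0.1, 2), "n")
})

test_that("MR power has correct size, monotonicity and closed form", {
  expect_equal(mr_power(1000, 0.02, 0, alpha = 0.05), 0.05, tolerance = 1e-12)
  grid_n <- sapply(c(1e4, 5e4, 1e5, 4e5), mr_power,
                   variance_explained = 0.02, causal_effect = 0.05)
  expect_true(all(diff(grid_n) > 0))
  grid_r2 <- sapply(c(0.01, 0.05, 0.2, 0.46), function(r2)
    mr_power(5000, r2, 0.05))
  expect_true(all(diff(grid_r2) > 0))
  expect_gt(mr_power(5000, 0.02, 0.1), mr_power(5000, 0.02, 0.05))
  # hand evaluation of the closed form
  ncp <- sqrt(2000 * 0.05) * 0.1
  expect_equal(mr_power(2000, 0.05, 0.1),
               1 - pnorm(qnorm(0.975) - ncp) + pnorm(-qnorm(0.975) - ncp),
               tolerance = 1e-12)
})

test_that("MR power matches a two-stage simulation oracle", {
  # continuous instrument, standardized exposure/outcome, ratio z-test
  set.seed(71)
  n <- 2000L; n_rep <- 3000L; r2 <- 0.05; theta <- 0.1
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    g <- rnorm(n)
    x <- sqrt(r2) * g + sqrt(1 - r2) * rnorm(n)
    y <- theta * x + sqrt(1 - theta^2) * rnorm(n)
    bgx <- cov(g, x) / var(g)
    fit <- summary(lm(y ~ g))
    z <- (fit$coefficients[2L, 1L] / bgx) / (fit$coefficients[2L, 2L] / abs(bgx))
    rejections <- rejections + (abs(z) > qnorm(0.975))
  }
  expect_lt(abs(rejections / n_rep - mr_power(n, r2, theta)), 0.03)
})

test_that("standard errors recovered from printed confidence intervals", {
  expect_equal(se_from_ci(-1.96, 1.96, 0.95), 1, tolerance = 1e-3)
  expect_equal(se_from_ci(0.103, 0.189), 0.0219, tolerance = 1e-2)
  expect_equal(se_from_ci(-0.341, -0.182), 0.0406, tolerance = 1e-2)
  expect_error(se_from_ci(1, 1), "smaller")
})

test_that("subgroup difference test is a two-sample z test", {
  same <- subgroup_difference_test(list(estimate = 0.5, se = 0.1),
                                   list(estimate = 0.5, se = 0.1))
  expect_identical(same$z, 0)
  expect_identical(same$p, 1)
  tst <- subgroup_difference_test(list(estimate = 1, se = 0.5),
                                  list(estimate = 0, se = 0.5))
  expect_equal(tst$z, sqrt(2), tolerance = 1e-12)
  expect_equal(tst$p, 0.157, tolerance = 1e-2)
  expect_error(subgroup_difference_test(list(estimate = 1, se = 0),
                                        list(estimate = 0, se = 1)),
               "positive")
})

test_that("bonferroni threshold divides the family-wise level", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_equal(signif(bonferroni_threshold(0.05, 9), 3), 0.00556, tolerance = 1e-12)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})
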