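test_that("covariate-free OLS equals the covariance/variance closed form", {
  tab <- toy_cohort(n = 200L, seed = 3L)
  fit <- fit_linear_snp_assoc(tab, "caffeine", "y", covariates = character())
  oracle <- cov(tab$dosage_caffeine, tab$y) / var(tab$dosage_caffeine)
  expect_equal(fit$beta, oracle, tolerance = 1e-10)
  expect_identical(fit$model, "linear")
  expect_identical(fit$n, 200L)
})

test_that("a known generating slope is recovered within sampling error", {
  tab <- toy_cohort(n = 5000L, seed = 11L, slope = 0.5)
  fit <- fit_linear_snp_assoc(tab, "caffeine", "y", covariates = character())
  expect_lt(abs(fit$beta - 0.5), 3 * fit$se)
  # same-draw closed-form oracle agrees to numerical precision
  oracle <- cov(tab$dosage_caffeine, tab$y) / var(tab$dosage_caffeine)
  expect_equal(fit$beta, oracle, tolerance = 1e-10)
})

test_that("null associations are calibrated and unaffected by independent covariates", {
  hits3 <- 0L
  for (i in seq_len(20L)) {
    tab <- toy_cohort(n = 4000L, seed = 100L + i, slope = 0)
    fit <- fit_linear_snp_assoc(tab, "caffeine", "y",
                                covariates = c("age", "sex"))
    hits3 <- hits3 + (abs(fit$beta) < 3 * fit$se)
    expect_lt(abs(fit$beta), 4.5 * fit$se)
  }
  expect_gte(hits3, 19L)

  tab <- toy_cohort(n = 5000L, seed = 31L, slope = 0.5)
  plain <- fit_linear_snp_assoc(tab, "caffeine", "y", covariates = character())
  with_pc <- fit_linear_snp_assoc(tab, "caffeine", "y", covariates = "pc1")
  expect_lt(abs(plain$beta - with_pc$beta), 0.2 * plain$se)
})

test_that("conditional and stratified fits are recorded and honoured", {
  tab <- toy_cohort(n = 4000L, seed = 17L)
  tab$other <- rnorm(nrow(tab))
  fit <- fit_linear_snp_assoc(tab, "caffeine", "y", covariates = "age",
                              condition_on = "other")
  expect_identical(fit$condition_on, "other")

  # two strata with genuinely different generating slopes
  set.seed(23)
  n <- 6000L
  g <- rbinom(n, 2L, 0.3)
  grp <- rbinom(n, 1L, 0.5)
  tab2 <- data.frame(dosage_caffeine = g, grp = grp,
                     y = ifelse(grp == 1L, 1.0, 0.2) * g + rnorm(n))
  in_strat <- fit_linear_snp_assoc(tab2, "caffeine", "y", covariates = character(),
                                   stratum_filter = function(t) t$grp == 1L,
                                   stratum = "grp1")
  out_strat <- fit_linear_snp_assoc(tab2, "caffeine", "y", covariates = character(),
                                    stratum_filter = function(t) t$grp == 0L)
  expect_identical(in_strat$stratum, "grp1")
  expect_lt(abs(in_strat$beta - 1.0), 3 * in_strat$se)
  expect_lt(abs(out_strat$beta - 0.2), 3 * out_strat$se)
  expect_gt(in_strat$beta, out_strat$beta)
})

test_that("degenerate designs fail with informative errors", {
  tab <- toy_cohort(n = 200L, seed = 5L)
  tab$dup <- tab$age
  expect_error(fit_linear_snp_assoc(tab, "caffeine", "y",
                                    covariates = c("age", "dup")),
               "collinear")
  tab$flat <- 1L
  expect_error(fit_linear_snp_assoc(tab, "flat", "y", covariates = character()),
               "constant dosage")
  expect_error(fit_linear_snp_assoc(tab[1:30, ], "caffeine", "y",
                                    covariates = character()),
               "fewer than 50")
  expect_error(fit_linear_snp_assoc(tab, "caffeine", "nope",
                                    covariates = character()),
               "nope")
})

test_that("logistic fit on a 2x2 table matches the contingency-table odds ratio", {
  # dosage dichotomized 0 vs >= 1; counts chosen by hand
  a <- 40L; b <- 60L; c_ <- 25L; d <- 75L   # exposed case/ctrl, unexposed case/ctrl
  tab <- data.frame(
    dosage_caffeine = rep(c(1L, 1L, 0L, 0L), c(a, b, c_, d)),
    status = rep(c(1L, 0L, 1L, 0L), c(a, b, c_, d))
  )
  fit <- fit_logistic_snp_assoc(tab, "caffeine", tab$status,
                                covariates = character())
  expect_equal(fit$beta, log((a / b) / (c_ / d)), tolerance = 1e-6)
  expect_equal(fit$se, sqrt(1 / a + 1 / b + 1 / c_ + 1 / d), tolerance = 1e-4)
})

test_that("logistic preconditions and separation are enforced", {
  coh <- harmonize_cohort(simulate_sample2(tiny_config(seed = 19L, n2 = 6000L)))
  fit <- fit_logistic_snp_assoc(coh, "caffeine", "coffee_status",
                                covariates = c("age", "sex"))
  expect_identical(fit$model, "logistic")
  expect_true(fit$n < nrow(coh))  # intermediates excluded

  small <- coh[1:200, ]
  small$rare <- c(rep(1L, 10L), rep(0L, 190L))
  expect_error(fit_logistic_snp_assoc(small, "caffeine", "rare",
                                      covariates = character()),
               "at least 25")

  sep <- data.frame(dosage_caffeine = rep(0:2, each = 60L))
  sep$status <- as.integer(sep$dosage_caffeine > 0L)
  expect_error(fit_logistic_snp_assoc(sep, "caffeine", sep$status,
                                      covariates = character()),
               "separation")
})

test_that("null logistic association is centred on zero", {
  set.seed(41)
  n <- 4000L
  tab <- data.frame(dosage_caffeine = rbinom(n, 2L, 0.3),
                    status = rbinom(n, 1L, 0.5))
  fit <- fit_logistic_snp_assoc(tab, "caffeine", tab$status,
                                covariates = character())
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("linear-score slopes convert to log odds ratios", {
  expect_identical(linear_to_log_or(0, 0.37), 0)
  expect_equal(linear_to_log_or(0.02, 0.2), 0.125)
  expect_error(linear_to_log_or(0.1, 0), "case_fraction")
  expect_error(linear_to_log_or(0.1, 1), "case_fraction")

  # approximation vs direct logistic fit, small effect, n = 50000
  set.seed(53)
  n <- 50000L
  g <- rbinom(n, 2L, 0.3)
  y <- rbinom(n, 1L, plogis(qlogis(0.2) + 0.1 * g))
  direct <- glm(y ~ g, family = binomial())
  beta_lin <- coef(lm(y ~ g))[2L]
  approx <- linear_to_log_or(beta_lin, mean(y))
  expect_lt(abs(approx - coef(direct)[2L]) / abs(coef(direct)[2L]), 0.1)
})
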