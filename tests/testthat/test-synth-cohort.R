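# One shared default-scale cohort for the file (seed fixed once).
s2_default <- simulate_sample2(default_cfg)

test_that("discovery-cohort ratings standardize and recover the instrument effects", {
  s1 <- simulate_sample1(default_cfg)
  expect_identical(nrow(s1), 1757L)
  for (s in bitter_stimuli()) {
    y <- s1[[paste0("intensity_", s)]]
    expect_lt(abs(mean(y)), 1e-8)          # empirical standardization
    expect_equal(sd(y), 1, tolerance = 1e-8)
    expect_true(all(s1[[paste0("rating_", s)]] >= 0))
    expect_true(all(s1[[paste0("dosage_", s)]] %in% 0:2))
  }
  slope <- coef(lm(intensity_prop ~ dosage_prop, data = s1))[2L]
  expect_gt(slope, 0.90)
  expect_lt(slope, 1.03)
})

test_that("a null instrument effect yields a flat taste association", {
  cfg0 <- simulation_config(
    seed = 9L,
    instrument_effects = c(prop = 0, quinine = 0.337, caffeine = 0.264),
    target_variance_explained = c(prop = 0, quinine = 0.05, caffeine = 0.02)
  )
  s1 <- simulate_sample1(cfg0)
  fit <- summary(lm(intensity_prop ~ dosage_prop, data = s1))
  expect_lt(abs(fit$coefficients[2L, 1L]), 3 * fit$coefficients[2L, 2L])
  expect_lt(fit$r.squared, 0.005)
})

test_that("variance explained is calibrated across seeds at the discovery scale", {
  r2 <- matrix(NA_real_, 50L, 3L, dimnames = list(NULL, bitter_stimuli()))
  for (i in seq_len(50L)) {
    s1 <- simulate_sample1(default_cfg, seed = 100L + i)
    for (s in bitter_stimuli()) {
      r2[i, s] <- summary(lm(s1[[paste0("intensity_", s)]] ~
                               s1[[paste0("dosage_", s)]]))$r.squared
    }
  }
  mean_r2 <- colMeans(r2)
  target <- default_cfg$target_variance_explained
  for (s in bitter_stimuli()) {
    expect_lt(abs(mean_r2[[s]] - target[[s]]) / target[[s]], 0.2)
  }
})

test_that("genotypes are in Hardy-Weinberg proportions across seeds", {
  crit <- qchisq(1 - 0.001, df = 1)
  exceed <- 0L
  total <- 0L
  for (i in seq_len(100L)) {
    coh <- simulate_sample2(default_cfg, seed = 2000L + i)
    for (s in bitter_stimuli()) {
      p <- default_cfg$allele_frequency[[s]]
      obs <- tabulate(coh[[paste0("dosage_", s)]] + 1L, 3L)
      exp_p <- c((1 - p)^2, 2 * p * (1 - p), p^2)
      stat <- sum((obs - nrow(coh) * exp_p)^2 / (nrow(coh) * exp_p))
      exceed <- exceed + (stat > crit)
      total <- total + 1L
    }
  }
  expect_lte(exceed / total, 0.01)
})

test_that("consumption cohort respects its schema invariants", {
  coh <- s2_default
  expect_identical(nrow(coh), 50000L)
  for (s in bitter_stimuli()) expect_true(all(coh[[paste0("dosage_", s)]] %in% 0:2))
  expect_true(all(coh$coffee_cups >= 0) && all(coh$tea_cups >= 0))
  expect_true(all(coh$coffee_cups == round(coh$coffee_cups)))
  expect_true(all(coh$alcohol_frequency %in%
                    c(alcohol_frequency_levels(), "Prefer not to answer")))
  expect_true(all(coh$sex %in% 0:1))
  # realized dosage variance matches the solved frequency (caffeine example)
  p <- default_cfg$allele_frequency[["caffeine"]]
  expect_equal(var(coh$dosage_caffeine), 2 * p * (1 - p), tolerance = 0.03)
  # alcohol categories follow the configured 6-vector
  freq <- table(factor(coh$alcohol_frequency, levels = alcohol_frequency_levels()))
  answered <- sum(freq)
  expect_equal(unname(as.vector(freq) / answered), default_cfg$alcohol_probs,
               tolerance = 0.05)
})

test_that("null causal effects leave the SNP-beverage slopes at zero", {
  cfg0 <- simulation_config(seed = 3L, n_sample2 = 20000L,
                            true_causal_effects = matrix(0, 3, 3))
  coh <- simulate_sample2(cfg0)
  for (s in bitter_stimuli()) {
    fit <- summary(lm(coh$coffee_cups ~ coh[[paste0("dosage_", s)]]))
    expect_lt(abs(fit$coefficients[2L, 1L]), 3.5 * fit$coefficients[2L, 2L])
  }
})

test_that("exclusion restriction holds by construction and breaks with the confounder switch", {
  # dosage conditional on the latent taste score carries no extra effect
  coefs <- ses <- numeric(20L)
  for (i in seq_len(20L)) {
    coh <- simulate_sample2(default_cfg, seed = 400L + i)
    fit <- summary(lm(coffee_cups ~ dosage_caffeine + taste_caffeine, data = coh))
    coefs[i] <- fit$coefficients["dosage_caffeine", 1L]
    ses[i] <- fit$coefficients["dosage_caffeine", 2L]
  }
  expect_lt(abs(mean(coefs)), 2.5 * mean(ses) / sqrt(20))

  # direct pleiotropic path: conditional dosage effect centred on the
  # configured per-allele value
  pl <- matrix(0, 3, 3, dimnames = list(bitter_stimuli(), beverage_outcomes()))
  pl["caffeine", "coffee"] <- 0.1
  cfgp <- simulation_config(seed = 6L, n_sample2 = 30000L, pleiotropy_effects = pl)
  direct <- dses <- numeric(10L)
  for (i in seq_len(10L)) {
    coh <- simulate_sample2(cfgp, seed = 900L + i)
    fit <- summary(lm(coffee_cups ~ dosage_caffeine + taste_caffeine, data = coh))
    direct[i] <- fit$coefficients["dosage_caffeine", 1L]
    dses[i] <- fit$coefficients["dosage_caffeine", 2L]
  }
  expect_lt(abs(mean(direct) - 0.1), 3 * mean(dses) / sqrt(10))
  expect_gt(mean(direct) / (mean(dses) / sqrt(10)), 5)  # clearly non-zero
})

test_that("identical seed and config give bit-identical cohorts", {
  a <- simulate_sample2(tiny_config(seed = 77L))
  b <- simulate_sample2(tiny_config(seed = 77L))
  expect_identical(a, b)
  c1 <- simulate_sample1(tiny_config(seed = 77L))
  c2 <- simulate_sample1(tiny_config(seed = 77L))
  expect_identical(c1, c2)
  # the two cohorts use distinct sub-streams of the master seed
  expect_false(identical(a$age[1:10], simulate_sample1(tiny_config(seed = 77L))$rating_prop[1:10]))
})

test_that("cohort export round-trips losslessly", {
  coh <- simulate_sample2(tiny_config(seed = 13L, n2 = 2000L))
  coh$alcohol_frequency[5L] <- NA
  path <- tempfile(fileext = ".tsv")
  export_cohort(coh, path, include_latent = TRUE)
  expect_identical(length(readLines(path)), nrow(coh) + 1L)

  back <- read_cohort(path)
  expect_identical(names(back), names(coh))
  for (j in names(coh)) expect_identical(back[[j]], coh[[j]], label = j)
  expect_true(is.na(back$alcohol_frequency[5L]))

  # latent oracle columns are withheld unless requested
  path2 <- tempfile(fileext = ".tsv")
  export_cohort(coh, path2)
  expect_false(any(grepl("taste_", readLines(path2, n = 1L))))
})

test_that("default full-size export has one line per participant plus header", {
  path <- tempfile(fileext = ".tsv")
  export_cohort(s2_default, path)
  expect_identical(length(readLines(path)), default_cfg$n_sample2 + 1L)
  unlink(path)
})
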