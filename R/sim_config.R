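## ---------------------------------------------------------------------------
## Floored-rounded normal calibration
##
## Observed cups/day are generated as Y = round(max(X, 0)) with X latent
## Gaussian. The helpers below give the exact discrete distribution of Y,
## its first two moments, the derivative of E[Y] with respect to a latent
## mean shift (used to pre-compensate genetic effects for truncation
## attenuation), and the cross moment of two such variables under a
## bivariate normal latent (used to calibrate the latent correlation so
## that the *observed* coffee-tea correlation hits its target).
## ---------------------------------------------------------------------------

fr_support <- function(mu, sigma) seq_len(max(1L, ceiling(mu + 9 * sigma)))

fr_moments <- function(mu, sigma) {
  k <- fr_support(mu, sigma)
  p0 <- stats::pnorm((0.5 - mu) / sigma)
  pk <- stats::pnorm((k + 0.5 - mu) / sigma) - stats::pnorm((k - 0.5 - mu) / sigma)
  kk <- c(0, k)
  p <- c(p0, pk)
  m <- sum(kk * p)
  c(mean = m, sd = sqrt(max(sum(kk^2 * p) - m^2, 0)))
}

## d E[round(max(X,0))] / d mu, closed form
fr_mean_slope <- function(mu, sigma) {
  k <- fr_support(mu, sigma)
  sum(k * (stats::dnorm((k - 0.5 - mu) / sigma) -
             stats::dnorm((k + 0.5 - mu) / sigma))) / sigma
}

## latent (mu, sigma) such that round(max(N(mu, sigma), 0)) has the target
## observed mean and SD
fr_match_moments <- function(target_mean, target_sd) {
  if (!is.finite(target_mean) || target_mean <= 0) {
    stop("infeasible marginal target: mean must be positive, got ", target_mean,
         call. = FALSE)
  }
  if (!is.finite(target_sd) || target_sd <= 0) {
    stop("infeasible marginal target: SD must be positive, got ", target_sd,
         call. = FALSE)
  }
  obj <- function(par) {
    mm <- fr_moments(par[1L], exp(par[2L]))
    (mm[["mean"]] - target_mean)^2 + (mm[["sd"]] - target_sd)^2
  }
  opt <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-15, maxit = 5000))
  if (opt$value > 1e-8) {
    stop(sprintf("infeasible marginal target: mean %g, SD %g cannot be matched by a zero-truncated rounded Gaussian",
                 target_mean, target_sd), call. = FALSE)
  }
  c(mu = opt$par[1L], sigma = exp(opt$par[2L]))
}

## Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  jac <- diag(0, n)
  jac[cbind(i, i + 1L)] <- b
  jac[cbind(i + 1L, i)] <- b
  e <- eigen(jac, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

## E[Y1 * Y2] for Yi = round(max(Xi, 0)), (X1, X2) bivariate normal
fr_cross_moment <- function(mu1, s1, mu2, s2, rho, quad = gauss_legendre(8L)) {
  k1 <- fr_support(mu1, s1)
  k2 <- fr_support(mu2, s2)
  sc <- s2 * sqrt(1 - rho^2)
  total <- 0
  for (j in k1) {
    x <- 0.5 * quad$x + j            # nodes over (j - 0.5, j + 0.5)
    w <- 0.5 * quad$w
    cm <- mu2 + rho * s2 * (x - mu1) / s1
    s_inner <- vapply(cm, function(m) {
      sum(k2 * (stats::pnorm((k2 + 0.5 - m) / sc) -
                  stats::pnorm((k2 - 0.5 - m) / sc)))
    }, numeric(1L))
    total <- total + j * sum(w * stats::dnorm(x, mu1, s1) * s_inner)
  }
  total
}

## latent correlation giving the target observed correlation
fr_match_correlation <- function(mu1, s1, mu2, s2, target_r) {
  m1 <- fr_moments(mu1, s1)
  m2 <- fr_moments(mu2, s2)
  f <- function(r) {
    (fr_cross_moment(mu1, s1, mu2, s2, r) - m1[["mean"]] * m2[["mean"]]) /
      (m1[["sd"]] * m2[["sd"]]) - target_r
  }
  stats::uniroot(f, c(-0.99, 0.99), tol = 1e-9)$root
}

## ---------------------------------------------------------------------------
## Allele-frequency solver
## ---------------------------------------------------------------------------

#' Solve the allele frequency implied by effect size and variance explained
#'
#' Under Hardy-Weinberg equilibrium an additive biallelic SNP with
#' per-allele effect `beta` on a unit-variance trait explains
#' `2 p (1 - p) beta^2` of the trait variance. This inverts that relation,
#' returning the root in (0, 0.5] (minor-allele convention).
#'
#' @param beta Per-allele effect on the standardized trait (SD units).
#' @param variance_explained Target proportion of variance explained.
#' @return Allele frequency in (0, 0.5].
#' @section Errors: If no real frequency attains the target (i.e.
#'   `variance_explained > beta^2 / 2`, the maximum at p = 0.5), an error is
#'   thrown; see [bitter_allele_frequencies()] for how the package's default
#'   configuration handles the one published instrument whose printed effect
#'   size and variance explained are jointly infeasible.
#' @export
solve_allele_frequency <- function(beta, variance_explained) {
  stopifnot(is.numeric(beta), is.numeric(variance_explained))
  if (variance_explained < 0) stop("`variance_explained` must be non-negative", call. = FALSE)
  if (beta == 0 && variance_explained == 0) {
    return(0.5)  # any frequency explains zero variance; maximum-heterozygosity convention
  }
  if (beta == 0 && variance_explained > 0) {
    stop("no allele frequency yields positive variance explained with a zero effect",
         call. = FALSE)
  }
  disc <- 1 - 2 * variance_explained / beta^2
  if (disc < 0) {
    stop(sprintf(
      "no real allele frequency solves 2p(1-p)*%.3f^2 = %.4f (maximum attainable variance explained is %.4f at p = 0.5)",
      beta, variance_explained, beta^2 / 2), call. = FALSE)
  }
  (1 - sqrt(disc)) / 2
}

#' Default allele frequencies for the built-in instruments
#'
#' Frequencies are solved from the published per-allele effects and variance
#' explained via [solve_allele_frequency()]. For quinine the published pair
#' (0.337 SD, 6% variance) is jointly infeasible under an additive
#' Hardy-Weinberg model (the maximum attainable variance explained is
#' `0.337^2 / 2 = 5.68%`), so the maximum-heterozygosity frequency 0.5 is
#' used, giving the closest attainable variance explained.
#'
#' @param instrument_effects Named per-allele effects (SD units) for
#'   `prop`, `quinine`, `caffeine`.
#' @param target_variance_explained Named variance-explained targets.
#' @return Named numeric vector of allele frequencies.
#' @export
bitter_allele_frequencies <- function(
    instrument_effects = c(prop = 0.965, quinine = 0.337, caffeine = 0.264),
    target_variance_explained = c(prop = 0.46, quinine = 0.06, caffeine = 0.02)) {
  out <- vapply(bitter_stimuli(), function(s) {
    beta <- instrument_effects[[s]]
    r2 <- target_variance_explained[[s]]
    if (r2 <= beta^2 / 2) solve_allele_frequency(beta, r2) else 0.5
  }, numeric(1L))
  names(out) <- bitter_stimuli()
  out
}

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

as_stim_vec <- function(x, name, default = 0) {
  s <- bitter_stimuli()
  if (is.null(x)) x <- rep(default, 3L)
  if (is.null(names(x))) {
    if (length(x) != 3L) stop(sprintf("`%s` must have 3 entries (prop, quinine, caffeine)", name), call. = FALSE)
    names(x) <- s
  }
  if (!all(s %in% names(x))) stop(sprintf("`%s` must be named for %s", name, paste(s, collapse = ", ")), call. = FALSE)
  x[s]
}

as_effect_matrix <- function(x, name) {
  s <- bitter_stimuli(); b <- beverage_outcomes()
  if (is.null(x)) x <- matrix(0, 3L, 3L, dimnames = list(s, b))
  x <- as.matrix(x)
  if (!all(dim(x) == c(3L, 3L))) {
    stop(sprintf("`%s` must be a 3x3 matrix (stimuli x beverages)", name), call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- s
  if (is.null(colnames(x))) colnames(x) <- b
  x[s, b]
}

#' Default true causal effects of bitter perception on beverage intake
#'
#' Effects are in beverage units (cups/day for coffee and tea, drinking
#' occasions/month for alcohol) per SD of perceived bitterness, calibrated
#' to the published UK Biobank MR estimates. Where a published estimate is
#' reported per effect allele, it is converted to the per-SD scale by
#' dividing by the instrument's per-allele taste effect. The quinine-alcohol
#' cell, for which only a weakly positive association compatible with the
#' null is reported, is set to +0.05 occasions/month.
#'
#' @return A 3x3 matrix, stimuli (prop, quinine, caffeine) by beverages
#'   (coffee, tea, alcohol).
#' @export
default_true_effects <- function() {
  eff <- c(prop = 0.965, quinine = 0.337, caffeine = 0.264)
  m <- cbind(
    coffee  = c(-0.021, -0.081, 0.146),               # per-SD as reported
    tea     = c(0.034, 0.028, -0.045) / eff,          # per-allele -> per-SD
    alcohol = c(-0.136 / eff[["prop"]], 0.05, -0.047 / eff[["caffeine"]])
  )
  rownames(m) <- bitter_stimuli()
  m
}

#' Configure the synthetic two-cohort generator
#'
#' Bundles and validates every parameter of the generator, and pre-computes
#' the deterministic calibration used by [simulate_sample1()] and
#' [simulate_sample2()]: allele frequencies, latent Gaussian parameters for
#' the zero-truncated rounded beverage marginals, the truncation-attenuation
#' compensation factors for genetic effects, the latent coffee-tea
#' correlation hitting the target observed correlation, and the alcohol
#' category thresholds.
#'
#' @param seed Master seed. Per-cohort sub-stream seeds are derived from it
#'   deterministically.
#' @param n_sample1 Discovery (taste GWAS) cohort size; default 1757.
#' @param n_sample2 Consumption cohort size; default 50000, a desk-scale
#'   stand-in for the 438870-participant biobank cohort (pass
#'   `n_sample2 = 438870` for full-scale runs).
#' @param instrument_effects Per-allele taste effects (SD units), named per
#'   stimulus; defaults 0.965 (prop), 0.337 (quinine), 0.264 (caffeine).
#' @param target_variance_explained Per-stimulus variance-explained targets;
#'   defaults 0.46, 0.06, 0.02.
#' @param allele_frequency Effect-allele frequencies. The default
#'   [bitter_allele_frequencies()] solves each frequency from effect size
#'   and variance explained where feasible. Pass `NULL` to force strict
#'   solving (which errors, naming the stimulus, when the pair is
#'   infeasible), or a named vector to override.
#' @param true_causal_effects 3x3 matrix of true causal effects (beverage
#'   units per SD of perception); default [default_true_effects()].
#' @param coffee_mean,coffee_sd,tea_mean,tea_sd Target observed marginal
#'   moments of cups/day; defaults 2.13 (2.1) and 3.51 (2.9).
#' @param coffee_tea_correlation Target observed Pearson correlation between
#'   coffee and tea cups/day; default -0.3.
#' @param alcohol_probs Probabilities of the six ordered alcohol-frequency
#'   categories (Never ... Daily or almost daily); must sum to 1. Defaults
#'   8.1, 11.4, 11.6, 25.3, 23.7, 19.9 percent.
#' @param age_mean,age_sd,male_proportion Covariate marginals; defaults
#'   56.5, 8.1 and 0.458.
#' @param n_pcs Number of genetic principal-component covariates (standard
#'   normal); default 10.
#' @param age_effects,sex_effects Optional named per-beverage effects of
#'   centred age (per year) and sex (male vs female) on consumption;
#'   default 0.
#' @param pc_effects Optional `n_pcs` x 3 matrix of PC effects on the
#'   beverages; default 0.
#' @param pleiotropy_effects Optional 3x3 matrix of *direct* per-allele
#'   dosage effects on the beverages, bypassing taste perception. All-zero
#'   (the default) enforces the exclusion restriction by construction;
#'   non-zero values deliberately violate it for robustness testing.
#' @param prefer_not_to_answer_rate Fraction of participants whose
#'   alcohol-frequency answer is "Prefer not to answer" (excluded
#'   downstream); default 0.002.
#' @param rating_shift,rating_scale Location/scale of the square-root-scale
#'   raw intensity ratings in the discovery cohort (the raw-scale
#'   distribution is a modelling convenience; only its standardized
#'   transform matters downstream).
#' @return A validated list of class `"sim_config"`; the `$calibration`
#'   element holds the derived generator constants.
#' @export
simulation_config <- function(seed = 1L,
                              n_sample1 = 1757L,
                              n_sample2 = 50000L,
                              instrument_effects = c(prop = 0.965, quinine = 0.337, caffeine = 0.264),
                              target_variance_explained = c(prop = 0.46, quinine = 0.06, caffeine = 0.02),
                              allele_frequency = bitter_allele_frequencies(instrument_effects, target_variance_explained),
                              true_causal_effects = default_true_effects(),
                              coffee_mean = 2.13, coffee_sd = 2.1,
                              tea_mean = 3.51, tea_sd = 2.9,
                              coffee_tea_correlation = -0.3,
                              alcohol_probs = c(0.081, 0.114, 0.116, 0.253, 0.237, 0.199),
                              age_mean = 56.5, age_sd = 8.1,
                              male_proportion = 0.458,
                              n_pcs = 10L,
                              age_effects = NULL, sex_effects = NULL,
                              pc_effects = NULL,
                              pleiotropy_effects = NULL,
                              prefer_not_to_answer_rate = 0.002,
                              rating_shift = 5, rating_scale = 1) {
  stim <- bitter_stimuli()
  bev <- beverage_outcomes()

  instrument_effects <- as_stim_vec(instrument_effects, "instrument_effects")
  target_variance_explained <- as_stim_vec(target_variance_explained, "target_variance_explained")
  for (s in stim) {
    r2 <- target_variance_explained[[s]]
    if (!is.finite(r2) || r2 < 0 || r2 >= 1) {
      stop("`target_variance_explained[", s, "]` must lie in [0, 1), got ", r2,
           call. = FALSE)
    }
  }

  if (is.null(allele_frequency)) {
    allele_frequency <- vapply(stim, function(s) {
      tryCatch(solve_allele_frequency(instrument_effects[[s]], target_variance_explained[[s]]),
               error = function(e) stop("stimulus '", s, "': ", conditionMessage(e), call. = FALSE))
    }, numeric(1L))
  }
  allele_frequency <- as_stim_vec(allele_frequency, "allele_frequency")
  for (s in stim) assert_scalar_prob(allele_frequency[[s]], paste0("allele_frequency[", s, "]"))

  ## joint consistency: explained variance cannot exceed total (unit) variance
  for (s in stim) {
    vg <- 2 * allele_frequency[[s]] * (1 - allele_frequency[[s]])
    if (vg * instrument_effects[[s]]^2 > 1) {
      stop("stimulus '", s, "': 2p(1-p)*beta^2 = ",
           signif(vg * instrument_effects[[s]]^2, 4),
           " exceeds the unit trait variance", call. = FALSE)
    }
  }

  true_causal_effects <- as_effect_matrix(true_causal_effects, "true_causal_effects")
  pleiotropy_effects <- as_effect_matrix(pleiotropy_effects, "pleiotropy_effects")
  age_effects <- as_stim_setup_bev(age_effects, "age_effects")
  sex_effects <- as_stim_setup_bev(sex_effects, "sex_effects")
  n_pcs <- as.integer(n_pcs)
  if (n_pcs < 0L) stop("`n_pcs` must be non-negative", call. = FALSE)
  if (is.null(pc_effects)) pc_effects <- matrix(0, n_pcs, 3L, dimnames = list(NULL, bev))
  pc_effects <- as.matrix(pc_effects)
  if (n_pcs > 0L && !all(dim(pc_effects) == c(n_pcs, 3L))) {
    stop("`pc_effects` must be an n_pcs x 3 matrix", call. = FALSE)
  }

  if (length(alcohol_probs) != 6L || any(alcohol_probs <= 0) || any(alcohol_probs >= 1)) {
    stop("`alcohol_probs` must be 6 probabilities in (0, 1)", call. = FALSE)
  }
  if (abs(sum(alcohol_probs) - 1) > 1e-9) {
    stop("`alcohol_probs` must sum to 1 (within 1e-9), got ", sum(alcohol_probs), call. = FALSE)
  }
  assert_scalar_prob(male_proportion, "male_proportion")
  assert_scalar_prob(prefer_not_to_answer_rate, "prefer_not_to_answer_rate", open = FALSE)
  if (!is.finite(coffee_tea_correlation) || abs(coffee_tea_correlation) >= 1) {
    stop("`coffee_tea_correlation` must lie in (-1, 1)", call. = FALSE)
  }
  if (age_sd <= 0) stop("infeasible marginal target: age SD must be positive", call. = FALSE)
  if (n_sample1 < 2 || n_sample2 < 2) stop("cohort sizes must be at least 2", call. = FALSE)
  if (rating_scale <= 0) stop("`rating_scale` must be positive", call. = FALSE)

  cfg <- list(
    seed = as.integer(seed), n_sample1 = as.integer(n_sample1),
    n_sample2 = as.integer(n_sample2),
    instrument_effects = instrument_effects,
    target_variance_explained = target_variance_explained,
    allele_frequency = allele_frequency,
    true_causal_effects = true_causal_effects,
    coffee_mean = coffee_mean, coffee_sd = coffee_sd,
    tea_mean = tea_mean, tea_sd = tea_sd,
    coffee_tea_correlation = coffee_tea_correlation,
    alcohol_probs = alcohol_probs,
    age_mean = age_mean, age_sd = age_sd,
    male_proportion = male_proportion, n_pcs = n_pcs,
    age_effects = age_effects, sex_effects = sex_effects,
    pc_effects = pc_effects,
    pleiotropy_effects = pleiotropy_effects,
    prefer_not_to_answer_rate = prefer_not_to_answer_rate,
    rating_shift = rating_shift, rating_scale = rating_scale
  )
  cfg$calibration <- build_calibration(cfg)
  class(cfg) <- "sim_config"
  cfg
}

as_stim_setup_bev <- function(x, name) {
  b <- beverage_outcomes()
  if (is.null(x)) x <- stats::setNames(rep(0, 3L), b)
  if (is.null(names(x))) {
    if (length(x) != 3L) stop(sprintf("`%s` must have 3 entries (coffee, tea, alcohol)", name), call. = FALSE)
    names(x) <- b
  }
  x[b]
}

## Derived generator constants. Everything here is deterministic in the
## configuration; no RNG is consumed.
build_calibration <- function(cfg) {
  stim <- bitter_stimuli()
  p <- cfg$allele_frequency
  beta <- cfg$instrument_effects
  v_g <- 2 * p * (1 - p)

  ## taste-score residual SDs so that each score has unit variance
  taste_resid_sd <- sqrt(pmax(1 - v_g * beta^2, 0))

  marg <- list(
    coffee = fr_match_moments(cfg$coffee_mean, cfg$coffee_sd),
    tea = fr_match_moments(cfg$tea_mean, cfg$tea_sd)
  )
  slope <- vapply(marg, function(m) fr_mean_slope(m[["mu"]], m[["sigma"]]), numeric(1L))

  ## latent-scale (compensated) coefficients and systematic variances
  bev2 <- c("coffee", "tea")
  theta_star <- sweep(cfg$true_causal_effects[, bev2, drop = FALSE], 2L, slope[bev2], "/")
  pi_star <- sweep(cfg$pleiotropy_effects[, bev2, drop = FALSE], 2L, slope[bev2], "/")

  cov_var <- cfg$age_sd^2  # age variance; sex and PC variances below
  sys_var <- vapply(bev2, function(b) {
    th <- theta_star[, b]; pi <- pi_star[, b]
    sum(th^2 + pi^2 * v_g + 2 * th * pi * beta * v_g) +
      cfg$age_effects[[b]]^2 * cov_var +
      cfg$sex_effects[[b]]^2 * cfg$male_proportion * (1 - cfg$male_proportion) +
      sum(cfg$pc_effects[, b]^2)
  }, numeric(1L))

  resid_var <- vapply(bev2, function(b) marg[[b]][["sigma"]]^2 - sys_var[[b]], numeric(1L))
  if (any(resid_var <= 0)) {
    stop("systematic effects exceed the target beverage variance; reduce effect sizes or increase the target SD",
         call. = FALSE)
  }

  rho_latent <- fr_match_correlation(marg$coffee[["mu"]], marg$coffee[["sigma"]],
                                     marg$tea[["mu"]], marg$tea[["sigma"]],
                                     cfg$coffee_tea_correlation)
  sys_cov <- sum(theta_star[, "coffee"] * theta_star[, "tea"] +
                   (theta_star[, "coffee"] * pi_star[, "tea"] +
                      theta_star[, "tea"] * pi_star[, "coffee"]) * beta * v_g +
                   pi_star[, "coffee"] * pi_star[, "tea"] * v_g) +
    cfg$age_effects[["coffee"]] * cfg$age_effects[["tea"]] * cov_var +
    cfg$sex_effects[["coffee"]] * cfg$sex_effects[["tea"]] *
      cfg$male_proportion * (1 - cfg$male_proportion) +
    sum(cfg$pc_effects[, "coffee"] * cfg$pc_effects[, "tea"])
  resid_rho <- (rho_latent * marg$coffee[["sigma"]] * marg$tea[["sigma"]] - sys_cov) /
    sqrt(resid_var[["coffee"]] * resid_var[["tea"]])
  if (abs(resid_rho) >= 1) {
    stop("target coffee-tea correlation is unattainable given the configured systematic effects",
         call. = FALSE)
  }

  ## alcohol: latent occasions/month scale matched to the recoded categories
  v <- alcohol_recode_values()
  mu_a <- sum(cfg$alcohol_probs * v)
  sd_a <- sqrt(sum(cfg$alcohol_probs * v^2) - mu_a^2)
  theta_a <- cfg$true_causal_effects[, "alcohol"]
  pi_a <- cfg$pleiotropy_effects[, "alcohol"]
  sys_var_a <- sum(theta_a^2 + pi_a^2 * v_g + 2 * theta_a * pi_a * beta * v_g) +
    cfg$age_effects[["alcohol"]]^2 * cov_var +
    cfg$sex_effects[["alcohol"]]^2 * cfg$male_proportion * (1 - cfg$male_proportion) +
    sum(cfg$pc_effects[, "alcohol"]^2)
  if (sys_var_a >= sd_a^2) {
    stop("alcohol systematic effects exceed the latent variance implied by the category probabilities",
         call. = FALSE)
  }
  thresholds <- stats::qnorm(cumsum(cfg$alcohol_probs)[1:5], mu_a, sd_a)

  list(
    taste_resid_sd = stats::setNames(taste_resid_sd, stim),
    dosage_var = stats::setNames(v_g, stim),
    coffee = list(mu = marg$coffee[["mu"]], sigma = marg$coffee[["sigma"]],
                  slope = slope[["coffee"]], theta_star = theta_star[, "coffee"],
                  pi_star = pi_star[, "coffee"], resid_sd = sqrt(resid_var[["coffee"]])),
    tea = list(mu = marg$tea[["mu"]], sigma = marg$tea[["sigma"]],
               slope = slope[["tea"]], theta_star = theta_star[, "tea"],
               pi_star = pi_star[, "tea"], resid_sd = sqrt(resid_var[["tea"]])),
    latent_rho = rho_latent, resid_rho = resid_rho,
    alcohol = list(mu = mu_a, sd = sd_a, resid_sd = sqrt(sd_a^2 - sys_var_a),
                   thresholds = thresholds, theta = theta_a, pi = pi_a)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic two-cohort simulation configuration\n")
  cat(sprintf("  seed %d | sample 1 (taste GWAS) n = %d | sample 2 (consumption) n = %d\n",
              x$seed, x$n_sample1, x$n_sample2))
  cat("  instruments (per-allele SD effect @ effect-allele frequency):\n")
  for (s in bitter_stimuli()) {
    cat(sprintf("    %-9s %.3f @ p = %.3f (target R2 %.3f)\n", s,
                x$instrument_effects[[s]], x$allele_frequency[[s]],
                x$target_variance_explained[[s]]))
  }
  cat(sprintf("  coffee %.2f (%.2f) cups/day, tea %.2f (%.2f) cups/day, r = %.2f\n",
              x$coffee_mean, x$coffee_sd, x$tea_mean, x$tea_sd,
              x$coffee_tea_correlation))
  cat("  true causal effects (beverage units per SD of perception):\n")
  print(round(x$true_causal_effects, 4))
  invisible(x)
}
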