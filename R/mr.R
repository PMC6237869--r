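mr_result <- function(stimulus, outcome, estimate, se, ci_low, ci_high, p,
                      scale = c("linear", "odds_ratio"), analysis = "main",
                      snp = NA_character_, n = NA_integer_,
                      se_mode = NA_character_, stratum = NA_character_) {
  scale <- match.arg(scale)
  p <- min(max(p, .Machine$double.xmin), 1)  # p in (0, 1]
  out <- data.frame(
    stimulus = as.character(stimulus), outcome = as.character(outcome),
    analysis = as.character(analysis), stratum = as.character(stratum),
    scale = scale,
    estimate = estimate, se = se, ci_low = ci_low, ci_high = ci_high,
    p = p, snp = as.character(snp), n = as.integer(n),
    se_mode = as.character(se_mode), stringsAsFactors = FALSE
  )
  class(out) <- c("mr_result", "data.frame")
  out
}

as_assoc_row <- function(assoc) {
  if (inherits(assoc, "snp_assoc") || is.data.frame(assoc)) {
    stopifnot(nrow(assoc) == 1L)
    as.list(assoc)
  } else if (is.list(assoc)) {
    assoc
  } else {
    stop("`assoc` must be an association result or a list with `beta` and `se`",
         call. = FALSE)
  }
}

wald_se <- function(beta_bev, se_bev, beta_bitter, se_bitter,
                    se_mode = c("full_delta", "first_order")) {
  se_mode <- match.arg(se_mode)
  if (se_mode == "first_order") {
    se_bev / abs(beta_bitter)
  } else {
    sqrt(se_bev^2 / beta_bitter^2 + beta_bev^2 * se_bitter^2 / beta_bitter^4)
  }
}

#' Single-instrument Wald ratio causal estimate
#'
#' The causal effect of a one-SD increase in perceived bitterness on a
#' continuous outcome: the per-allele SNP-outcome association divided by
#' the per-allele instrument effect on the standardized taste rating.
#' Standard errors come from the delta method, with zero cross-covariance
#' between numerator and denominator (two-sample design):
#' `first_order` scales the outcome SE by `1/|beta_bitter|` (treating the
#' instrument effect as known; this is the scaling consistent with simple
#' division of a published CI), while `full_delta` (default) adds the
#' instrument-uncertainty term
#' `beta_bev^2 * se_bitter^2 / beta_bitter^4`. The 95% CI is
#' `estimate +/- 1.96 * SE` and the p-value uses the normal approximation.
#'
#' @param assoc A linear `"snp_assoc"` result (or list with `beta`, `se`,
#'   optionally `n`, `phenotype`).
#' @param instrument A one-row [genetic_instrument()].
#' @param se_mode `"full_delta"` or `"first_order"`.
#' @return A one-row `"mr_result"` data frame on the linear scale
#'   (outcome units per SD of perceived bitterness).
#' @export
wald_ratio <- function(assoc, instrument, se_mode = c("full_delta", "first_order")) {
  se_mode <- match.arg(se_mode)
  a <- as_assoc_row(assoc)
  if (!is.null(a$model) && a$model != "linear") {
    stop("`assoc` must come from a linear model; use causal_or() for binary contrasts",
         call. = FALSE)
  }
  stopifnot(nrow(instrument) == 1L)
  if (instrument$beta_bitter == 0) {
    stop("undefined Wald ratio: instrument effect is zero", call. = FALSE)
  }
  est <- a$beta / instrument$beta_bitter
  se <- wald_se(a$beta, a$se, instrument$beta_bitter, instrument$se_bitter, se_mode)
  z <- stats::qnorm(0.975)
  mr_result(
    stimulus = instrument$stimulus, outcome = a$phenotype %||% NA_character_,
    estimate = est, se = se, ci_low = est - z * se, ci_high = est + z * se,
    p = 2 * stats::pnorm(-abs(est / se)), scale = "linear",
    snp = instrument$snp, n = a$n %||% NA_integer_, se_mode = se_mode
  )
}

#' Causal odds ratio for a drinker-status contrast
#'
#' Wald ratio on the log-odds scale,
#' `log OR_wald = log OR_drinkstatus / beta_bitter`, then exponentiated;
#' the CI is exponentiated from the symmetric log-scale bounds. `se` in the
#' result remains on the log scale.
#'
#' @param assoc A `"snp_assoc"` result with `model` `"logistic"` or
#'   `"linear_approx_logOR"`; `beta` is the per-allele log odds ratio.
#' @param instrument A one-row [genetic_instrument()].
#' @param se_mode `"full_delta"` or `"first_order"` (see [wald_ratio()]).
#' @return A one-row `"mr_result"` with `scale = "odds_ratio"`: `estimate`,
#'   `ci_low`, `ci_high` are odds ratios per SD of perceived bitterness.
#' @export
causal_or <- function(assoc, instrument, se_mode = c("full_delta", "first_order")) {
  se_mode <- match.arg(se_mode)
  a <- as_assoc_row(assoc)
  if (!is.null(a$model) && !a$model %in% c("logistic", "linear_approx_logOR")) {
    stop("`assoc` must be a logistic or linear_approx_logOR result", call. = FALSE)
  }
  stopifnot(nrow(instrument) == 1L)
  if (instrument$beta_bitter == 0) {
    stop("undefined Wald ratio: instrument effect is zero", call. = FALSE)
  }
  log_est <- a$beta / instrument$beta_bitter
  log_se <- wald_se(a$beta, a$se, instrument$beta_bitter, instrument$se_bitter, se_mode)
  z <- stats::qnorm(0.975)
  mr_result(
    stimulus = instrument$stimulus, outcome = a$phenotype %||% NA_character_,
    estimate = exp(log_est), se = log_se,
    ci_low = exp(log_est - z * log_se), ci_high = exp(log_est + z * log_se),
    p = 2 * stats::pnorm(-abs(log_est / log_se)), scale = "odds_ratio",
    snp = instrument$snp, n = a$n %||% NA_integer_, se_mode = se_mode
  )
}

#' Two-sided power of a single-instrument MR analysis
#'
#' Normal-approximation power with non-centrality
#' `sqrt(n * R2) * causal_effect` on the standardized scale (exposure and
#' outcome in SD units):
#' `power = 1 - pnorm(z_crit - ncp) + pnorm(-z_crit - ncp)`.
#'
#' @param n Outcome-sample size.
#' @param variance_explained Instrument R-squared on the exposure.
#' @param causal_effect Standardized causal effect (SD outcome per SD
#'   exposure).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1); equals `alpha` under the null.
#' @export
mr_power <- function(n, variance_explained, causal_effect, alpha = 0.05) {
  if (n <= 0) stop("`n` must be positive", call. = FALSE)
  assert_scalar_prob(alpha, "alpha")
  if (variance_explained <= 0 || variance_explained >= 1) {
    stop("`variance_explained` must lie in (0, 1)", call. = FALSE)
  }
  ncp <- sqrt(n * variance_explained) * causal_effect
  z_crit <- stats::qnorm(1 - alpha / 2)
  1 - stats::pnorm(z_crit - ncp) + stats::pnorm(-z_crit - ncp)
}

#' Recover a standard error from a printed confidence interval
#'
#' `se = (high - low) / (2 * z)` with `z` the `(1 + level)/2` normal
#' quantile — the inverse of a symmetric Wald interval. Used to re-analyse
#' published estimates for which only the CI is reported.
#'
#' @param low,high Interval bounds, `low < high`.
#' @param level Confidence level, default 0.95.
#' @return The implied standard error.
#' @export
se_from_ci <- function(low, high, level = 0.95) {
  if (any(low >= high)) stop("`low` must be smaller than `high`", call. = FALSE)
  assert_scalar_prob(level, "level")
  (high - low) / (2 * stats::qnorm((1 + level) / 2))
}

#' Test the difference between two subgroup estimates
#'
#' Independent-samples z test:
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)` with a two-sided normal
#' p-value. Used for sex differences; when applied to conditional-versus
#' -original contrasts the two estimates share a sample and the test is
#' only a heuristic (a caveat is attached to the result).
#'
#' @param est1,est2 `"mr_result"` rows, or lists with `estimate` and `se`.
#'   Odds-ratio results are compared on the log scale (their `se` is
#'   already log-scale).
#' @return A list with `z`, `p`, and the difference `delta`.
#' @export
subgroup_difference_test <- function(est1, est2) {
  get_es <- function(e) {
    if (inherits(e, "mr_result") || is.data.frame(e)) {
      stopifnot(nrow(e) == 1L)
      est <- if (!is.null(e$scale) && e$scale == "odds_ratio") log(e$estimate) else e$estimate
      list(est = est, se = e$se, scale = e$scale %||% "linear")
    } else {
      list(est = e$estimate, se = e$se, scale = e$scale %||% "linear")
    }
  }
  a <- get_es(est1)
  b <- get_es(est2)
  if (!identical(a$scale, b$scale)) {
    stop("both estimates must be on the same scale", call. = FALSE)
  }
  if (!is.finite(a$se) || !is.finite(b$se) || a$se <= 0 || b$se <= 0) {
    stop("standard errors must be positive", call. = FALSE)
  }
  delta <- a$est - b$est
  z <- delta / sqrt(a$se^2 + b$se^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), delta = delta)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 9L) {
  assert_scalar_prob(alpha, "alpha")
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  alpha / m
}
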