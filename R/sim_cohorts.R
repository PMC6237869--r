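#' Simulate the taste-GWAS discovery cohort (sample 1)
#'
#' Generates unrelated individuals with one biallelic SNP per bitter
#' stimulus (Hardy-Weinberg genotypes at the configured frequency), raw
#' intensity ratings on a non-negative scale, and the
#' square-root-transformed, empirically standardized rating used as the
#' GWAS phenotype. Per-allele effects act on the standardized scale, so a
#' simple regression of `intensity_<stimulus>` on `dosage_<stimulus>`
#' recovers the configured instrument effect up to sampling error.
#'
#' Raw ratings are produced by mapping the standardized latent score back
#' through the inverse of the square-root transform
#' (`rating = max(shift + scale * latent, 0)^2`), so the transform is
#' well-defined and the flooring is negligible at the default location.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this cohort; defaults to the "sample1" sub-stream
#'   derived from `config$seed`.
#' @return A data frame with columns `id`, `dosage_<stimulus>`,
#'   `rating_<stimulus>` (raw scale) and `intensity_<stimulus>`
#'   (standardized SD units) for each stimulus.
#' @export
simulate_sample1 <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seeds(config$seed)[1L]
  set.seed(as.integer(seed))
  n <- config$n_sample1
  cal <- config$calibration
  out <- data.frame(id = sprintf("S1_%05d", seq_len(n)), stringsAsFactors = FALSE)
  for (s in bitter_stimuli()) {
    p <- config$allele_frequency[[s]]
    beta <- config$instrument_effects[[s]]
    g <- stats::rbinom(n, 2L, p)
    latent <- beta * (g - 2 * p) + stats::rnorm(n, 0, cal$taste_resid_sd[[s]])
    sqrt_raw <- config$rating_shift + config$rating_scale * latent
    rating <- pmax(sqrt_raw, 0)^2
    out[[paste0("dosage_", s)]] <- g
    out[[paste0("rating_", s)]] <- rating
    out[[paste0("intensity_", s)]] <- as.numeric(scale(sqrt(rating)))
  }
  out
}

#' Simulate the consumption cohort (sample 2)
#'
#' Generates a UK-Biobank-like cohort of unrelated individuals: genotype
#' dosages at the three instrument SNPs, age, sex, genetic principal
#' components, coffee and tea cups/day, and a six-category alcohol-frequency
#' answer. The genotype-to-beverage pathway runs exclusively through the
#' latent taste score times the configured true causal effect, so the
#' exclusion restriction holds by construction unless
#' `pleiotropy_effects` is set.
#'
#' Coffee and tea are rounded, zero-truncated draws from latent Gaussians.
#' The latent parameters are calibrated (see [simulation_config()]) so that
#' the *observed* marginal moments and coffee-tea correlation match their
#' targets, and genetic effects are pre-compensated for the attenuation
#' induced by truncation and rounding, so that the per-allele regression
#' slope on the observed scale equals `true_effect * beta_bitter`.
#'
#' The latent taste scores are retained as `taste_<stimulus>` columns for
#' parameter-recovery checks; they are oracle-only quantities that no
#' analysis step may use, and [export_cohort()] omits them by default.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this cohort; defaults to the "sample2" sub-stream
#'   derived from `config$seed`.
#' @return A data frame with columns `id`, `age`, `sex` (1 = male),
#'   `pc1..pcK`, `dosage_<stimulus>`, `coffee_cups`, `tea_cups`,
#'   `alcohol_frequency`, and oracle columns `taste_<stimulus>`.
#' @export
simulate_sample2 <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seeds(config$seed)[2L]
  set.seed(as.integer(seed))
  n <- config$n_sample2
  cal <- config$calibration
  stim <- bitter_stimuli()

  dosage <- sapply(stim, function(s) stats::rbinom(n, 2L, config$allele_frequency[[s]]))
  taste <- sapply(stim, function(s) {
    config$instrument_effects[[s]] * (dosage[, s] - 2 * config$allele_frequency[[s]]) +
      stats::rnorm(n, 0, cal$taste_resid_sd[[s]])
  })
  centred_dosage <- sweep(dosage, 2L, 2 * config$allele_frequency)

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- as.integer(stats::runif(n) < config$male_proportion)
  pcs <- if (config$n_pcs > 0L) {
    matrix(stats::rnorm(n * config$n_pcs), n, config$n_pcs)
  } else {
    matrix(0, n, 0L)
  }

  covariate_shift <- function(bev) {
    config$age_effects[[bev]] * (age - config$age_mean) +
      config$sex_effects[[bev]] * (sex - config$male_proportion) +
      if (config$n_pcs > 0L) drop(pcs %*% config$pc_effects[, bev]) else 0
  }

  z1 <- stats::rnorm(n)
  z2 <- cal$resid_rho * z1 + sqrt(1 - cal$resid_rho^2) * stats::rnorm(n)
  latent_coffee <- cal$coffee$mu + drop(taste %*% cal$coffee$theta_star) +
    drop(centred_dosage %*% cal$coffee$pi_star) + covariate_shift("coffee") +
    cal$coffee$resid_sd * z1
  latent_tea <- cal$tea$mu + drop(taste %*% cal$tea$theta_star) +
    drop(centred_dosage %*% cal$tea$pi_star) + covariate_shift("tea") +
    cal$tea$resid_sd * z2

  latent_alcohol <- cal$alcohol$mu + drop(taste %*% cal$alcohol$theta) +
    drop(centred_dosage %*% cal$alcohol$pi) + covariate_shift("alcohol") +
    stats::rnorm(n, 0, cal$alcohol$resid_sd)
  category <- alcohol_frequency_levels()[
    findInterval(latent_alcohol, cal$alcohol$thresholds) + 1L]
  if (config$prefer_not_to_answer_rate > 0) {
    pnta <- stats::runif(n) < config$prefer_not_to_answer_rate
    category[pnta] <- "Prefer not to answer"
  }

  out <- data.frame(id = sprintf("S2_%06d", seq_len(n)),
                    age = age, sex = sex, stringsAsFactors = FALSE)
  if (config$n_pcs > 0L) {
    colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
    out <- cbind(out, as.data.frame(pcs))
  }
  for (s in stim) out[[paste0("dosage_", s)]] <- dosage[, s]
  out$coffee_cups <- round(pmax(latent_coffee, 0))
  out$tea_cups <- round(pmax(latent_tea, 0))
  out$alcohol_frequency <- category
  for (s in stim) out[[paste0("taste_", s)]] <- taste[, s]
  out
}

oracle_columns <- function() paste0("taste_", bitter_stimuli())

#' Write a cohort table to a tab-separated file
#'
#' Numeric columns are written with 17 significant digits so that the file
#' round-trips losslessly through [read_cohort()]. Missing values are
#' written as empty fields. Oracle-only latent columns (`taste_*`) are
#' omitted unless `include_latent = TRUE`.
#'
#' @param table A cohort data frame.
#' @param path Output file path.
#' @param include_latent Keep the oracle-only latent taste columns?
#' @return `path`, invisibly.
#' @export
export_cohort <- function(table, path, include_latent = FALSE) {
  stopifnot(is.data.frame(table))
  if (!include_latent) table <- table[, setdiff(names(table), oracle_columns()), drop = FALSE]
  fmt <- table
  for (j in names(fmt)) {
    if (is.numeric(fmt[[j]])) {
      v <- sprintf("%.17g", fmt[[j]])
      v[is.na(fmt[[j]])] <- NA_character_
      fmt[[j]] <- v
    }
  }
  ok <- tryCatch({
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop("cannot write cohort table to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
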