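#' Construct a SNP-phenotype association result
#'
#' Container for a per-effect-allele SNP-phenotype estimate: the numerator
#' (or denominator) of a Wald ratio. `beta` is on the phenotype scale for
#' linear models and on the log-odds scale for `logistic` and
#' `linear_approx_logOR` models.
#'
#' @param snp SNP or dosage-column identifier.
#' @param phenotype Phenotype name.
#' @param beta Per-effect-allele estimate.
#' @param se Standard error (positive).
#' @param n Number of observations used.
#' @param model One of `"linear"`, `"logistic"`, `"linear_approx_logOR"`.
#' @param covariates Character vector of adjustment covariates.
#' @param condition_on Optional conditioning phenotype (conditional
#'   analyses).
#' @param stratum Optional stratum label.
#' @return A one-row data frame of class `"snp_assoc"`.
#' @export
association_result <- function(snp, phenotype, beta, se, n,
                               model = c("linear", "logistic", "linear_approx_logOR"),
                               covariates = character(), condition_on = NA_character_,
                               stratum = NA_character_) {
  model <- match.arg(model)
  if (!is.finite(se) || se <= 0) stop("`se` must be positive", call. = FALSE)
  n_par <- 2L + length(covariates) + as.integer(!is.na(condition_on))
  if (n <= n_par) stop("`n` must exceed the number of model parameters", call. = FALSE)
  out <- data.frame(
    snp = as.character(snp), phenotype = as.character(phenotype),
    model = model, beta = beta, se = se, n = as.integer(n),
    covariates = paste(covariates, collapse = ","),
    condition_on = as.character(condition_on),
    stratum = as.character(stratum), stringsAsFactors = FALSE
  )
  class(out) <- c("snp_assoc", "data.frame")
  out
}

#' Default adjustment covariates
#'
#' Age, sex and the first `n_pcs` genetic principal components — the
#' standard adjustment set for biobank SNP-phenotype regressions.
#'
#' @param n_pcs Number of principal components; default 10.
#' @return Character vector of column names.
#' @export
default_covariates <- function(n_pcs = 10L) {
  c("age", "sex", if (n_pcs > 0L) paste0("pc", seq_len(n_pcs)))
}

resolve_dosage_column <- function(table, snp) {
  cand <- c(paste0("dosage_", tolower(snp)), snp)
  hit <- cand[cand %in% names(table)]
  if (!length(hit)) {
    stop("no dosage column found for `", snp,
         "` (looked for ", paste(sQuote(cand), collapse = ", "), ")", call. = FALSE)
  }
  hit[1L]
}

apply_stratum_filter <- function(table, stratum_filter) {
  if (is.null(stratum_filter)) return(rep(TRUE, nrow(table)))
  keep <- if (is.function(stratum_filter)) stratum_filter(table) else stratum_filter
  if (!is.logical(keep) || length(keep) != nrow(table)) {
    stop("`stratum_filter` must be (or return) a logical vector with one entry per row",
         call. = FALSE)
  }
  keep & !is.na(keep)
}

build_design <- function(table, dosage_col, outcome_col, covariates, condition_on) {
  vars <- c(outcome_col, dosage_col, covariates, condition_on)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- table[, vars, drop = FALSE]
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Fit a per-allele linear SNP-phenotype association
#'
#' Ordinary least squares of the phenotype on the effect-allele dosage,
#' adjusted for covariates (and, for conditional analyses, the conditioning
#' phenotype as a further regressor). Rows with any missing regressor or
#' outcome are dropped (complete-case analysis). The standard error is the
#' usual OLS estimator.
#'
#' @param table Cohort data frame.
#' @param snp Stimulus name (resolved to `dosage_<snp>`) or a dosage column
#'   name.
#' @param phenotype Outcome column name.
#' @param covariates Adjustment covariate names; default
#'   [default_covariates()].
#' @param condition_on Optional phenotype column added as a regressor.
#' @param stratum_filter Optional logical vector, or function of the table
#'   returning one, restricting the analysis to a stratum.
#' @param stratum Label recorded for the stratum.
#' @return A `"snp_assoc"` result (see [association_result()]).
#' @export
fit_linear_snp_assoc <- function(table, snp, phenotype,
                                 covariates = default_covariates(),
                                 condition_on = NULL, stratum_filter = NULL,
                                 stratum = NA_character_) {
  dosage_col <- resolve_dosage_column(table, snp)
  keep <- apply_stratum_filter(table, stratum_filter)
  df <- build_design(table[keep, , drop = FALSE], dosage_col, phenotype,
                     covariates, condition_on)
  if (nrow(df) < 50L) {
    stop("fewer than 50 usable rows after missing-data exclusion and stratum filtering",
         call. = FALSE)
  }
  if (stats::var(df[[dosage_col]]) == 0) {
    stop("constant dosage column `", dosage_col, "` in the analysis sample",
         call. = FALSE)
  }
  rhs <- paste(c(dosage_col, covariates, condition_on), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste(phenotype, "~", rhs)), data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear design; offending column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  association_result(
    snp = dosage_col, phenotype = phenotype,
    beta = sm[dosage_col, "Estimate"], se = sm[dosage_col, "Std. Error"],
    n = nrow(df), model = "linear", covariates = covariates,
    condition_on = condition_on %||% NA_character_, stratum = stratum
  )
}

#' Fit a per-allele logistic SNP association for a drinker-status contrast
#'
#' Maximum-likelihood logistic regression of heavy (1) versus light/non (0)
#' status on the effect-allele dosage with covariate adjustment;
#' intermediate participants are excluded. Convergence follows the IRLS
#' criterion (relative deviance change below 1e-8, at most 100 iterations);
#' the standard error comes from the observed information.
#'
#' @param table Cohort data frame.
#' @param snp Stimulus name or dosage column name.
#' @param status Name of a status column (factor with levels
#'   `light_or_non`/`intermediate`/`heavy`, as produced by
#'   [dichotomize_drinkers()]), or such a factor, or a 0/1 vector.
#' @param covariates Adjustment covariate names.
#' @param stratum_filter,stratum As in [fit_linear_snp_assoc()].
#' @return A `"snp_assoc"` result with `model = "logistic"`; `beta` is the
#'   per-allele log odds ratio.
#' @export
fit_logistic_snp_assoc <- function(table, snp, status,
                                   covariates = default_covariates(),
                                   stratum_filter = NULL,
                                   stratum = NA_character_) {
  dosage_col <- resolve_dosage_column(table, snp)
  status_name <- if (is.character(status) && length(status) == 1L) status else "status"
  y_raw <- if (is.character(status) && length(status) == 1L) {
    if (is.null(table[[status]])) stop("no status column `", status, "`", call. = FALSE)
    table[[status]]
  } else {
    status
  }
  y <- if (is.factor(y_raw) || is.character(y_raw)) {
    lab <- as.character(y_raw)
    ifelse(lab == "heavy", 1L, ifelse(lab == "light_or_non", 0L, NA_integer_))
  } else {
    as.integer(y_raw)
  }
  if (any(!y %in% c(0L, 1L) & !is.na(y))) {
    stop("`status` must be heavy/light_or_non labels or a 0/1 vector", call. = FALSE)
  }
  keep <- apply_stratum_filter(table, stratum_filter)
  tab <- table[keep, , drop = FALSE]
  tab$.y <- y[keep]
  df <- build_design(tab, dosage_col, ".y", covariates, NULL)
  n_case <- sum(df$.y == 1L)
  n_ctrl <- sum(df$.y == 0L)
  if (n_case < 25L || n_ctrl < 25L) {
    stop(sprintf("need at least 25 observations in each outcome class (got %d cases, %d controls)",
                 n_case, n_ctrl), call. = FALSE)
  }
  if (stats::var(df[[dosage_col]]) == 0) {
    stop("constant dosage column `", dosage_col, "` in the analysis sample", call. = FALSE)
  }
  rhs <- paste(c(dosage_col, covariates), collapse = " + ")
  fit <- suppressWarnings(stats::glm(
    stats::as.formula(paste(".y ~", rhs)), data = df, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)
  ))
  sm <- summary(fit)$coefficients
  if (!fit$converged || sm[dosage_col, "Std. Error"] > 50) {
    stop("logistic fit did not converge (possible complete separation); a larger sample is needed",
         call. = FALSE)
  }
  association_result(
    snp = dosage_col, phenotype = status_name,
    beta = sm[dosage_col, "Estimate"], se = sm[dosage_col, "Std. Error"],
    n = nrow(df), model = "logistic", covariates = covariates,
    stratum = stratum
  )
}

#' Convert a linear-model case-indicator slope to a log odds ratio
#'
#' First-order approximation used when a binary trait has been analysed
#' with a linear (mixed) model: the per-allele change in the case indicator
#' divided by `mu * (1 - mu)`, where `mu` is the case fraction. The
#' approximation is accurate for small effects (roughly `|log OR| < 0.3`).
#'
#' @param beta_linear Per-allele change in the 0/1 case indicator.
#' @param case_fraction Proportion of cases, strictly in (0, 1).
#' @return The approximate log odds ratio.
#' @export
linear_to_log_or <- function(beta_linear, case_fraction) {
  if (any(case_fraction <= 0) || any(case_fraction >= 1)) {
    stop("`case_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  beta_linear / (case_fraction * (1 - case_fraction))
}
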