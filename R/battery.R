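#' Default analysis plan mirroring the published study structure
#'
#' Main linear analyses (3 stimuli x 3 beverages), heavy-versus-light/non
#' binary contrasts, conditional analyses for the coffee-tea substitution
#' (each beverage adjusted for the other), stratified analyses among
#' non-consumers of the other beverage, and by-sex analyses.
#'
#' @param conditional Include the conditional coffee|tea and tea|coffee
#'   cells?
#' @param strata Include the non-tea-drinker / non-coffee-drinker strata?
#' @param by_sex Include sex-stratified analyses of the linear outcomes?
#' @param binary Include the drinker-status contrasts?
#' @return A list of class `"mr_plan"`.
#' @export
default_analysis_plan <- function(conditional = TRUE, strata = TRUE,
                                  by_sex = TRUE, binary = TRUE) {
  plan <- list(
    linear_outcomes = c(coffee = "coffee_cups", tea = "tea_cups",
                        alcohol = "alcohol_times_month"),
    binary_contrasts = if (binary) {
      c(coffee = "coffee_status", tea = "tea_status", alcohol = "alcohol_status")
    } else {
      character()
    },
    conditional = if (conditional) {
      list(list(outcome = "coffee_cups", adjust = "tea_cups"),
           list(outcome = "tea_cups", adjust = "coffee_cups"))
    } else {
      list()
    },
    strata = if (strata) {
      list(
        non_tea_drinkers = list(outcome = "coffee_cups",
                                filter = function(tab) tab$tea_cups == 0),
        non_coffee_drinkers = list(outcome = "tea_cups",
                                   filter = function(tab) tab$coffee_cups == 0)
      )
    } else {
      list()
    },
    by_sex = by_sex
  )
  class(plan) <- c("mr_plan", "list")
  plan
}

battery_cell <- function(cohort, instrument, covariates, se_mode,
                         outcome = NULL, status = NULL, condition_on = NULL,
                         stratum_filter = NULL, stratum = NA_character_,
                         analysis = "main") {
  assoc <- if (is.null(status)) {
    fit_linear_snp_assoc(cohort, instrument$stimulus, outcome,
                         covariates = covariates, condition_on = condition_on,
                         stratum_filter = stratum_filter, stratum = stratum)
  } else {
    fit_logistic_snp_assoc(cohort, instrument$stimulus, status,
                           covariates = covariates,
                           stratum_filter = stratum_filter, stratum = stratum)
  }
  res <- if (is.null(status)) {
    wald_ratio(assoc, instrument, se_mode)
  } else {
    causal_or(assoc, instrument, se_mode)
  }
  res$analysis <- analysis
  res$stratum <- stratum
  list(mr = res, assoc = assoc)
}

#' Run the full battery of MR analyses on a cohort
#'
#' One Wald-ratio causal estimate per stimulus x outcome x analysis cell of
#' the plan. Cells whose preconditions fail (e.g. an empty stratum) are
#' skipped with a warning. Every result is flagged against the Bonferroni
#' threshold for the main test family (`alpha / family_size`, with
#' `family_size` defaulting to the number of main linear cells, i.e. 9);
#' cells beyond the main battery are exploratory and the flag is advisory
#' there.
#'
#' @param cohort A harmonized cohort table (see [harmonize_cohort()]).
#' @param instruments A `"genetic_instrument"` table, one row per stimulus
#'   (e.g. [bitter_instruments()] or [estimate_instruments()]).
#' @param plan An analysis plan, default [default_analysis_plan()].
#' @param covariates Adjustment covariates; default [default_covariates()].
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @param family_size Number of tests in the main family; default the
#'   number of main linear cells.
#' @param se_mode Delta-method mode for the Wald SE.
#' @return An `"mr_result"` data frame, one row per completed cell, with a
#'   `pass_bonferroni` column and the fitted SNP-phenotype associations
#'   attached as `attr(, "associations")`.
#' @export
run_mr_battery <- function(cohort, instruments, plan = default_analysis_plan(),
                           covariates = default_covariates(),
                           alpha = 0.05, family_size = NULL,
                           se_mode = c("full_delta", "first_order")) {
  se_mode <- match.arg(se_mode)
  stopifnot(is.data.frame(instruments), nrow(instruments) >= 1L)
  if (!inherits(plan, "mr_plan")) stop("`plan` must be an analysis plan", call. = FALSE)
  family_size <- family_size %||% (nrow(instruments) * length(plan$linear_outcomes))
  threshold <- bonferroni_threshold(alpha, family_size)

  results <- list()
  assocs <- list()
  push <- function(cell) {
    results[[length(results) + 1L]] <<- cell$mr
    assocs[[length(assocs) + 1L]] <<- cell$assoc
  }
  try_cell <- function(label, expr) {
    tryCatch(push(expr), error = function(e) {
      warning("skipping cell ", label, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  for (i in seq_len(nrow(instruments))) {
    ins <- instruments[i, , drop = FALSE]
    for (out_col in plan$linear_outcomes) {
      try_cell(paste(ins$stimulus, out_col, "main"),
               battery_cell(cohort, ins, covariates, se_mode, outcome = out_col))
    }
    for (st_col in plan$binary_contrasts) {
      try_cell(paste(ins$stimulus, st_col, "main"),
               battery_cell(cohort, ins, covariates, se_mode, status = st_col))
    }
    for (cc in plan$conditional) {
      try_cell(paste(ins$stimulus, cc$outcome, "conditional"),
               battery_cell(cohort, ins, covariates, se_mode,
                            outcome = cc$outcome, condition_on = cc$adjust,
                            analysis = "conditional"))
    }
    for (nm in names(plan$strata)) {
      st <- plan$strata[[nm]]
      try_cell(paste(ins$stimulus, st$outcome, nm),
               battery_cell(cohort, ins, covariates, se_mode,
                            outcome = st$outcome, stratum_filter = st$filter,
                            stratum = nm, analysis = "stratified"))
    }
    if (isTRUE(plan$by_sex)) {
      for (out_col in plan$linear_outcomes) {
        for (lab in c("male", "female")) {
          sx <- if (lab == "male") 1L else 0L
          try_cell(paste(ins$stimulus, out_col, lab),
                   battery_cell(cohort, ins, setdiff(covariates, "sex"), se_mode,
                                outcome = out_col,
                                stratum_filter = cohort$sex == sx,
                                stratum = lab, analysis = "by_sex"))
        }
      }
    }
  }

  if (!length(results)) {
    stop("no analysis cell completed; check the plan against the cohort schema",
         call. = FALSE)
  }
  out <- do.call(rbind, results)
  out$pass_bonferroni <- out$p < threshold
  attr(out, "bonferroni_threshold") <- threshold
  attr(out, "associations") <- do.call(rbind, assocs)
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Sex-difference tests from a battery result
#'
#' Applies [subgroup_difference_test()] to every stimulus x outcome pair
#' with both male and female `by_sex` estimates.
#'
#' @param battery An `"mr_result"` table from [run_mr_battery()].
#' @return A data frame with one row per pair: estimates, z and p.
#' @export
sex_difference_tests <- function(battery) {
  bs <- battery[battery$analysis == "by_sex", , drop = FALSE]
  if (!nrow(bs)) return(data.frame())
  key <- unique(bs[, c("stimulus", "outcome")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    m <- bs[bs$stimulus == key$stimulus[i] & bs$outcome == key$outcome[i], ]
    male <- m[m$stratum == "male", , drop = FALSE]
    female <- m[m$stratum == "female", , drop = FALSE]
    if (nrow(male) != 1L || nrow(female) != 1L) return(NULL)
    tst <- subgroup_difference_test(female, male)
    data.frame(stimulus = key$stimulus[i], outcome = key$outcome[i],
               estimate_female = female$estimate, estimate_male = male$estimate,
               z = tst$z, p = tst$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
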