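cohort_schema <- function(n_pcs = 10L) {
  c(
    id = "character", age = "numeric", sex = "integer",
    stats::setNames(rep("numeric", n_pcs), paste0("pc", seq_len(n_pcs))),
    stats::setNames(rep("integer", 3L), paste0("dosage_", bitter_stimuli())),
    coffee_cups = "numeric", tea_cups = "numeric",
    alcohol_frequency = "character",
    alcohol_times_month = "numeric",
    coffee_status = "character", tea_status = "character",
    alcohol_status = "character",
    stats::setNames(rep("numeric", 3L), paste0("taste_", bitter_stimuli()))
  )
}

#' Read a cohort table from a tab-separated file
#'
#' Columns are typed according to the documented cohort schema; empty
#' fields become missing values. Columns outside the schema are dropped
#' with a warning; required columns that are absent raise an error naming
#' them. A malformed numeric field raises an error with its line number.
#'
#' @param path Path to a tab-separated cohort file with a header row.
#' @param required Column names that must be present; defaults to the
#'   genotype and beverage columns needed by the analysis battery.
#' @return A typed cohort data frame.
#' @export
read_cohort <- function(path,
                        required = c(paste0("dosage_", bitter_stimuli()),
                                     "coffee_cups", "tea_cups",
                                     "alcohol_frequency")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", colClasses = "character",
                           na.strings = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  schema <- cohort_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (j in names(raw)) {
    type <- schema[[j]]
    if (type %in% c("numeric", "integer")) {
      num <- suppressWarnings(as.numeric(raw[[j]]))
      bad <- which(!is.na(raw[[j]]) & is.na(num))
      if (length(bad)) {
        stop(sprintf("malformed value '%s' in column `%s` at line %d of %s",
                     raw[[j]][bad[1L]], j, bad[1L] + 1L, path), call. = FALSE)
      }
      raw[[j]] <- if (type == "integer") as.integer(num) else num
    }
  }
  raw
}

#' Assemble and validate a pipeline run configuration
#'
#' Exactly one input source must be active: either `cohort_path` (an
#' existing consumption-cohort file) or `simulate` (a [simulation_config()]
#' or a list of arguments for one). When a cohort file is supplied the
#' instruments default to the built-in published table
#' ([bitter_instruments()]) unless `instruments_path` is given; when
#' simulating, the instruments are re-estimated from the simulated
#' discovery cohort (two-sample design).
#'
#' @param seed Master seed for the run.
#' @param simulate A [simulation_config()], a list of arguments for one, or
#'   `TRUE` for all defaults.
#' @param cohort_path Path to an existing cohort file.
#' @param instruments_path Optional instrument table path.
#' @param plan [default_analysis_plan()] by default.
#' @param alpha,family_size,se_mode Passed to [run_mr_battery()].
#' @param covariates Adjustment covariates.
#' @return A validated list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, simulate = TRUE, cohort_path = NULL,
                       instruments_path = NULL,
                       plan = default_analysis_plan(),
                       alpha = 0.05, family_size = NULL,
                       se_mode = "full_delta",
                       covariates = default_covariates()) {
  sim_active <- !is.null(simulate) && !isFALSE(simulate)
  if (sim_active && !is.null(cohort_path)) {
    stop("exactly one of `simulate` and `cohort_path` may be active", call. = FALSE)
  }
  if (!sim_active && is.null(cohort_path)) {
    stop("one of `simulate` and `cohort_path` must be supplied", call. = FALSE)
  }
  sim_cfg <- NULL
  if (sim_active) {
    sim_cfg <- if (inherits(simulate, "sim_config")) {
      simulate
    } else if (isTRUE(simulate)) {
      simulation_config(seed = seed)
    } else if (is.list(simulate)) {
      simulate$seed <- simulate$seed %||% seed
      do.call(simulation_config, simulate)
    } else {
      stop("`simulate` must be TRUE, a simulation_config, or a list of arguments",
           call. = FALSE)
    }
  }
  out <- list(seed = as.integer(seed), simulate = sim_cfg,
              cohort_path = cohort_path, instruments_path = instruments_path,
              plan = plan, alpha = alpha, family_size = family_size,
              se_mode = se_mode, covariates = covariates)
  class(out) <- "run_config"
  out
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys: `seed`, `cohort_path`, `instruments_path`,
#' `alpha`, `family_size`, `se_mode`, `covariates`, a `simulate` block of
#' [simulation_config()] arguments (where `true_causal_effects` and
#' `pleiotropy_effects` may be given as named lists of per-stimulus
#' 3-vectors keyed by beverage), and a `plan` block of
#' [default_analysis_plan()] switches (`conditional`, `strata`, `by_sex`,
#' `binary`).
#'
#' @param path YAML file path.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulate %||% is.null(y$cohort_path)
  if (is.list(sim)) {
    for (f in c("true_causal_effects", "pleiotropy_effects")) {
      if (!is.null(sim[[f]]) && is.list(sim[[f]])) {
        sim[[f]] <- sapply(beverage_outcomes(), function(b) unlist(sim[[f]][[b]]))
      }
    }
  }
  plan_args <- y$plan %||% list()
  run_config(
    seed = y$seed %||% 1L, simulate = sim, cohort_path = y$cohort_path,
    instruments_path = y$instruments_path,
    plan = do.call(default_analysis_plan, plan_args),
    alpha = y$alpha %||% 0.05, family_size = y$family_size,
    se_mode = y$se_mode %||% "full_delta",
    covariates = y$covariates %||% default_covariates()
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full generate / harmonize / associate / MR pipeline
#'
#' Orchestrates one reproducible end-to-end run: obtain the consumption
#' cohort (simulated or read from `cohort_path`), obtain the instruments
#' (estimated from a simulated discovery cohort, read from
#' `instruments_path`, or the built-in published table), harmonize the
#' beverage phenotypes, run the MR battery, and write all artifacts to
#' `output_dir`: `cohort.tsv`, `sample1.tsv` (if simulated),
#' `instruments.tsv`, `associations.tsv`, `mr_results.tsv`,
#' `sex_differences.tsv`, a human-readable `summary.txt` (point estimates
#' and 95% CIs per stimulus x beverage, linear and odds-ratio panels) and
#' `manifest.json` (seed, configuration hash, versions, row counts).
#' Identical seed and configuration give byte-identical tables. On failure
#' all partial outputs are removed.
#'
#' @param config A `"run_config"` (see [run_config()] /
#'   [read_run_config()]) or a YAML path.
#' @param output_dir Directory for the result bundle (created if needed).
#' @param quiet Suppress stage-boundary log messages?
#' @return Invisibly, a list with `cohort`, `instruments`, `battery`,
#'   `sex_differences` and the output paths.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
    p
  }

  tryCatch({
    sample1 <- NULL
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      note("simulating discovery cohort (n = %d) and consumption cohort (n = %d), seed %d",
           sim$n_sample1, sim$n_sample2, sim$seed)
      sample1 <- simulate_sample1(sim)
      cohort <- simulate_sample2(sim)
      instruments <- estimate_instruments(sample1)
      p <- file.path(output_dir, "sample1.tsv")
      export_cohort(sample1, p)
      written <- c(written, p)
      p <- file.path(output_dir, "cohort.tsv")
      export_cohort(cohort, p)
      written <- c(written, p)
    } else {
      note("reading cohort from %s", config$cohort_path)
      cohort <- read_cohort(config$cohort_path)
      instruments <- if (!is.null(config$instruments_path)) {
        read_instruments(config$instruments_path)
      } else {
        bitter_instruments()
      }
    }
    note("cohort rows: %d", nrow(cohort))

    cohort <- harmonize_cohort(cohort)
    excluded <- sum(is.na(cohort$alcohol_times_month))
    note("harmonized phenotypes; %d participant(s) without usable alcohol frequency", excluded)

    emit(as.data.frame(instruments), "instruments.tsv")
    battery <- run_mr_battery(cohort, instruments, plan = config$plan,
                              covariates = config$covariates,
                              alpha = config$alpha,
                              family_size = config$family_size,
                              se_mode = config$se_mode)
    note("MR battery: %d cell(s), Bonferroni threshold %.3g",
         nrow(battery), attr(battery, "bonferroni_threshold"))
    sexdiff <- sex_difference_tests(battery)

    emit(as.data.frame(attr(battery, "associations")), "associations.tsv")
    emit(as.data.frame(battery), "mr_results.tsv")
    if (is.data.frame(sexdiff) && nrow(sexdiff)) emit(sexdiff, "sex_differences.tsv")

    summary_path <- file.path(output_dir, "summary.txt")
    writeLines(format_mr_summary(battery, attr(battery, "bonferroni_threshold")),
               summary_path)
    written <- c(written, summary_path)

    cohort_file <- if (!is.null(config$simulate)) file.path(output_dir, "cohort.tsv") else config$cohort_path
    manifest <- list(
      package = "bittermr",
      package_version = as.character(utils::packageVersion("bittermr")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      simulated = !is.null(config$simulate),
      n_cohort = nrow(cohort),
      alpha = config$alpha,
      bonferroni_threshold = attr(battery, "bonferroni_threshold"),
      se_mode = config$se_mode,
      config_hash = unname(tools::md5sum(file.path(output_dir, "mr_results.tsv"))),
      cohort_hash = unname(tools::md5sum(cohort_file))
    )
    if (!is.null(config$simulate)) {
      manifest$sim <- config$simulate[c("n_sample1", "n_sample2", "seed")]
    }
    manifest_path <- file.path(output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, manifest_path)

    invisible(list(cohort = cohort, instruments = instruments,
                   battery = battery, sex_differences = sexdiff,
                   paths = written))
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed (partial outputs removed): ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Format a battery result as a forest-plot-style text summary
#'
#' @param battery An `"mr_result"` table.
#' @param threshold Bonferroni threshold used for the significance marker.
#' @return Character vector of report lines.
#' @export
format_mr_summary <- function(battery, threshold = attr(battery, "bonferroni_threshold") %||% 0.05 / 9) {
  lines <- c("Causal effects of perceived bitterness on beverage consumption",
             sprintf("(Wald ratio per SD of perception; * = p < %.3g)", threshold), "")
  for (panel in c("linear", "odds_ratio")) {
    sub <- battery[battery$scale == panel & battery$analysis == "main", , drop = FALSE]
    if (!nrow(sub)) next
    lines <- c(lines, if (panel == "linear") "Consumption (beverage units/day or occasions/month):"
               else "Heavy vs light/non drinker status (causal OR):")
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf(
        "  %-9s -> %-20s %8.3f [%7.3f, %7.3f]%s",
        sub$stimulus[i], sub$outcome[i], sub$estimate[i],
        sub$ci_low[i], sub$ci_high[i],
        if (sub$p[i] < threshold) " *" else ""))
    }
    lines <- c(lines, "")
  }
  lines
}
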