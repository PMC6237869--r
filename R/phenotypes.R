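#' The six ordered alcohol-frequency categories
#'
#' Vocabulary of the touch-screen question "About how often do you drink
#' alcohol?", from least to most frequent.
#'
#' @return Character vector of the six labels.
#' @export
alcohol_frequency_levels <- function() {
  c("Never", "Special occasions only", "1-3 times a month",
    "1-2 times a week", "3-4 times a week", "Daily or almost daily")
}

alcohol_recode_values <- function() c(0, 1, 2, 6, 15, 30)

normalize_alcohol_label <- function(x) {
  x <- gsub("[\u2013\u2014]", "-", x)  # en/em-dash variants of the printed labels
  x <- gsub("\\s+", " ", trimws(x))
  x
}

#' Recode alcohol-frequency categories to drinking occasions per month
#'
#' Maps the six ordered categories to monthly frequencies:
#' Never = 0, Special occasions only = 1, 1-3 times a month = 2,
#' 1-2 times a week = 6, 3-4 times a week = 15, Daily or almost daily = 30.
#' "Prefer not to answer" and missing values propagate as `NA` (those
#' participants are excluded downstream). The mapping is total on its
#' vocabulary and idempotent: numeric input already in the codomain is
#' returned unchanged.
#'
#' @param category Character vector of category labels (en-dash variants
#'   accepted), or numeric vector already on the occasions/month scale.
#' @return Numeric vector of occasions per month.
#' @export
recode_alcohol_frequency <- function(category) {
  values <- alcohol_recode_values()
  if (is.numeric(category)) {
    bad <- !is.na(category) & !category %in% values
    if (any(bad)) {
      stop("unrecognized alcohol frequency value(s): ",
           paste(unique(category[bad]), collapse = ", "), call. = FALSE)
    }
    return(as.numeric(category))
  }
  if (is.factor(category)) category <- as.character(category)
  x <- normalize_alcohol_label(category)
  out <- values[match(x, alcohol_frequency_levels())]
  pnta <- !is.na(x) & tolower(x) == "prefer not to answer"
  unknown <- is.na(out) & !is.na(x) & !pnta
  if (any(unknown)) {
    stop("unrecognized alcohol frequency label(s): ",
         paste(sQuote(unique(category[unknown])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Average repeat assessments of a phenotype
#'
#' Participants assessed at multiple visits contribute the arithmetic mean
#' of their non-missing measurements; a participant with no non-missing
#' measurement yields `NA`.
#'
#' @param values Numeric vector (or list) of repeat measurements for one
#'   participant.
#' @return A single phenotype value, or `NA` if all entries are missing.
#' @export
average_repeat_assessments <- function(values) {
  values <- unlist(values, use.names = FALSE)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  mean(values)
}

#' Fixed drinker-status cutoffs
#'
#' The published 20th/80th-percentile-based cutoffs: coffee < 2 (light/non)
#' and > 4 (heavy) cups/day; tea < 2 and > 5 cups/day. Values exactly at a
#' cutoff are intermediate (the strict inequalities are read literally).
#'
#' @param beverage `"coffee"` or `"tea"`.
#' @return Numeric `c(low, high)`.
#' @export
fixed_drinker_cutoffs <- function(beverage = c("coffee", "tea")) {
  switch(match.arg(beverage), coffee = c(low = 2, high = 4), tea = c(low = 2, high = 5))
}

#' Classify participants as light/non, intermediate or heavy consumers
#'
#' In `"fixed"` mode the published cutoffs are applied verbatim: coffee
#' < 2 cups/day light/non and > 4 heavy; tea < 2 and > 5; for alcohol,
#' "Never" is a non-drinker and only "Daily or almost daily" (more frequent
#' than 3-4 times a week) is heavy. In `"percentile"` mode the 20th and
#' 80th percentiles of the supplied table's distribution are used instead.
#' Participants strictly between the cutoffs are `intermediate` and are
#' excluded from binary contrasts downstream; values exactly at a cutoff
#' are intermediate (strict inequalities).
#'
#' @param table Cohort data frame with `coffee_cups`, `tea_cups` and/or
#'   `alcohol_frequency` columns.
#' @param beverage One of `"coffee"`, `"tea"`, `"alcohol"`.
#' @param mode `"fixed"` (published cutoffs) or `"percentile"` (20th/80th
#'   of the supplied table).
#' @param cutoffs Optional `c(low, high)` override (e.g. for sensitivity
#'   analyses with alternative cutoffs); ignored for alcohol in fixed mode.
#' @return A factor with levels `light_or_non`, `intermediate`, `heavy`
#'   (missing phenotype gives `NA`), with a `"cutoffs"` attribute.
#' @export
dichotomize_drinkers <- function(table, beverage = c("coffee", "tea", "alcohol"),
                                 mode = c("fixed", "percentile"), cutoffs = NULL) {
  beverage <- match.arg(beverage)
  mode <- match.arg(mode)
  lv <- c("light_or_non", "intermediate", "heavy")

  if (beverage == "alcohol" && mode == "fixed" && is.null(cutoffs)) {
    raw <- table[["alcohol_frequency"]]
    if (is.null(raw)) stop("`table` lacks an `alcohol_frequency` column", call. = FALSE)
    monthly <- recode_alcohol_frequency(raw)
    status <- ifelse(is.na(monthly), NA_character_,
                     ifelse(monthly == 0, "light_or_non",
                            ifelse(monthly > 15, "heavy", "intermediate")))
    out <- factor(status, levels = lv)
    attr(out, "cutoffs") <- c(low = 0, high = 15)
    return(out)
  }

  col <- switch(beverage, coffee = "coffee_cups", tea = "tea_cups",
                alcohol = "alcohol_times_month")
  x <- table[[col]]
  if (is.null(x)) {
    if (beverage == "alcohol" && !is.null(table[["alcohol_frequency"]])) {
      x <- recode_alcohol_frequency(table[["alcohol_frequency"]])
    } else {
      stop("`table` lacks a `", col, "` column", call. = FALSE)
    }
  }

  if (is.null(cutoffs)) {
    if (mode == "fixed") {
      cutoffs <- fixed_drinker_cutoffs(beverage)
    } else {
      cutoffs <- stats::quantile(x, c(0.2, 0.8), na.rm = TRUE, names = FALSE)
      if (diff(cutoffs) <= 0) {
        stop("degenerate percentiles (20th and 80th coincide); use fixed mode or explicit cutoffs",
             call. = FALSE)
      }
    }
  }
  if (length(cutoffs) != 2L || cutoffs[1L] >= cutoffs[2L]) {
    stop("`cutoffs` must be c(low, high) with low < high", call. = FALSE)
  }
  status <- ifelse(is.na(x), NA_character_,
                   ifelse(x < cutoffs[1L], "light_or_non",
                          ifelse(x > cutoffs[2L], "heavy", "intermediate")))
  out <- factor(status, levels = lv)
  attr(out, "cutoffs") <- c(low = unname(cutoffs[1L]), high = unname(cutoffs[2L]))
  out
}

#' Harmonize beverage phenotypes on a cohort table
#'
#' Adds the derived phenotype columns used by the analysis battery:
#' `alcohol_times_month` (recoded monthly frequency, `NA` for "Prefer not
#' to answer") and the fixed-mode drinker-status columns `coffee_status`,
#' `tea_status`, `alcohol_status`.
#'
#' @param table Cohort data frame (see [simulate_sample2()] /
#'   [read_cohort()] for the schema).
#' @return The table with the derived columns appended.
#' @export
harmonize_cohort <- function(table) {
  stopifnot(is.data.frame(table))
  if (!is.null(table[["alcohol_frequency"]])) {
    table$alcohol_times_month <- recode_alcohol_frequency(table$alcohol_frequency)
    table$alcohol_status <- dichotomize_drinkers(table, "alcohol", "fixed")
  }
  if (!is.null(table[["coffee_cups"]])) {
    table$coffee_status <- dichotomize_drinkers(table, "coffee", "fixed")
  }
  if (!is.null(table[["tea_cups"]])) {
    table$tea_status <- dichotomize_drinkers(table, "tea", "fixed")
  }
  table
}
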