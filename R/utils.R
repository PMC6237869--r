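`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bitter stimuli handled by the package
#'
#' The three bitter compounds with a confirmed single-SNP genetic proxy for
#' perceived intensity: propylthiouracil (PROP, TAS2R38 locus), quinine and
#' caffeine (both tagged by SNPs in the chromosome-12 bitter-receptor
#' cluster).
#'
#' @return Character vector `c("prop", "quinine", "caffeine")`.
#' @export
bitter_stimuli <- function() c("prop", "quinine", "caffeine")

#' Beverage outcomes handled by the package
#'
#' @return Character vector `c("coffee", "tea", "alcohol")`.
#' @export
beverage_outcomes <- function() c("coffee", "tea", "alcohol")

## Deterministic per-cohort sub-streams from one master seed, so that the
## discovery cohort and the consumption cohort never share RNG draws.
substream_seeds <- function(seed, n = 2L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

assert_scalar_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) stop(sprintf("`%s` must lie in (0, 1), got %g", name, x), call. = FALSE)
  invisible(x)
}
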