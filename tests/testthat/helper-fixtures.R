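# Small configurations reused across test files. Fixed seeds; nothing here
# depends on test outcomes.

tiny_config <- function(seed = 42L, n2 = 4000L, ...) {
  simulation_config(seed = seed, n_sample2 = n2, ...)
}

# cached default config (calibration is deterministic, so share it)
default_cfg <- simulation_config(seed = 1L)

with_cfg_n2 <- function(cfg, n2) {
  args <- unclass(cfg)
  args$calibration <- NULL
  args$n_sample2 <- as.integer(n2)
  do.call(simulation_config, args)
}

# toy cohort with hand-made columns for unit tests of the fitting layer
toy_cohort <- function(n = 5000L, seed = 7L, slope = 0.5, p = 0.3,
                       noise_sd = 1) {
  set.seed(seed)
  g <- rbinom(n, 2L, p)
  data.frame(
    id = sprintf("T%05d", seq_len(n)),
    age = rnorm(n, 50, 5), sex = rbinom(n, 1L, 0.5),
    pc1 = rnorm(n),
    dosage_caffeine = g,
    y = slope * g + rnorm(n, 0, noise_sd)
  )
}
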