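# Small cohorts used across the suite. Sizes are deliberately modest so
# the whole suite stays fast; the acceptance tests use larger ones.

tiny_spec <- function(seed = 1L, ...) {
  args <- list(n_per_group = 6L, n_regions = 12L, n_discriminative = 3L,
               n_timepoints = 120L, n_features = 4L, effect_size = 1.5,
               beta_sd = 0.5, noise_sd = 4, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

tiny_cohort <- function(seed = 1L, ...) {
  make_cohort(tiny_spec(seed = seed, ...))
}

# mean CV accuracy of the full decoder on a fresh cohort
cohort_cv_accuracy <- function(spec, n_top = spec$n_discriminative,
                               n_runs = 1L, seed = spec$seed) {
  cv <- run_cv(make_cohort(spec), n_top_regions = n_top, n_runs = n_runs,
               seed = seed)
  cv$mean_metrics[["accuracy"]]
}
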