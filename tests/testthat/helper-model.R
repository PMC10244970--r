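# Shared model components, built once per test run. Calibration of the
# default bank takes ~1 s, so tests reuse these instead of rebuilding.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(filter_family = "biphasic") {
  key <- filter_family
  if (is.null(.model_cache[[key]])) {
    bank <- build_channel_bank()
    filt <- switch(filter_family,
                   biphasic = make_biphasic_filter(),
                   lowpass = make_lowpass_filter())
    mapping <- calibrate_baseline(bank, filt)
    .model_cache[[key]] <- list(bank = bank, filter = filt, mapping = mapping)
  }
  .model_cache[[key]]
}

# Design comparison levels used throughout (signed % of standard).
design_levels_pct <- function() round(comparison_levels_pct(experiment_design()), 2)

# Simulate one observer's trial set at the design structure.
sim_observer_trials <- function(mu, sigma, reps = 20, seed = 1) {
  x <- rep(design_levels_pct(), each = reps)
  r <- with_seed_local(seed, stats::rbinom(length(x), 1, stats::pnorm((x - mu) / sigma)))
  list(x = x, response = r)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
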