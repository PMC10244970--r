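#' Default model configuration
#'
#' A nested list of every tunable constant of the model and experiment
#' design, suitable for serializing to YAML and overriding from a file.
#'
#' @return A named list with components `design`, `filter`, `bank`.
#' @export
default_model_config <- function() {
  list(
    design = list(
      standards_ms = c(600, 1200),
      comparison_fractions = c(1 / 3, 2 / 3, 5 / 6, 1, 7 / 6, 4 / 3, 5 / 3),
      min_reps = 20,
      adaptor_contrast = 0.5,
      test_contrast = 0.8,
      test_tf_hz = 10,
      adaptor_tf_hz = c(5, 20),
      segment_ms = 500,
      initial_adapt_s = 32,
      topup_adapt_s = 8,
      isi_ms = 500
    ),
    filter = list(
      family = "biphasic",
      tau_e_ms = 8, n_e = 9, tau_i_ms = 10, n_i = 10,
      inhib_weight = 0.9, sample_rate = 1000, kernel_ms = 400
    ),
    bank = list(
      n_channels = 61, min_width_ms = 50, max_width_ms = 4000,
      spacing = "log", window_shape = "raisedcos",
      transducer = list(p = 2.4, q = 2, z = 1, w = 1),
      adapt_strength = 0.6, adapt_sat = 2, adapt_exponent = 2,
      adapt_rule = "linear"
    )
  )
}

#' Read a model configuration from a YAML file
#'
#' Values found in the file override the defaults; anything omitted keeps
#' its default. Requires the `yaml` package.
#'
#' @param path Path to a YAML file.
#' @return A configuration list as from [default_model_config()].
#' @export
read_model_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(default_model_config(), user)
}

#' Build model components from a configuration
#'
#' @param config A configuration list (see [default_model_config()]).
#' @return A list with `design` ([experiment_design()]), `filter`
#'   ([make_biphasic_filter()] or [make_lowpass_filter()]), and `bank`
#'   ([build_channel_bank()]).
#' @export
build_from_config <- function(config = default_model_config()) {
  d <- config$design
  design <- experiment_design(
    standards_ms = d$standards_ms,
    comparison_fractions = d$comparison_fractions,
    min_reps = d$min_reps,
    adaptor_contrast = d$adaptor_contrast,
    test_contrast = d$test_contrast,
    test_tf_hz = d$test_tf_hz,
    adaptor_tf_hz = d$adaptor_tf_hz,
    segment_ms = d$segment_ms,
    initial_adapt_s = d$initial_adapt_s,
    topup_adapt_s = d$topup_adapt_s,
    isi_ms = d$isi_ms
  )
  f <- config$filter
  filter <- if (identical(f$family, "lowpass")) {
    make_lowpass_filter(tau_ms = if (is.null(f$tau_ms)) 20 else f$tau_ms,
                        sample_rate = f$sample_rate, kernel_ms = f$kernel_ms)
  } else {
    make_biphasic_filter(tau_e_ms = f$tau_e_ms, n_e = f$n_e,
                         tau_i_ms = f$tau_i_ms, n_i = f$n_i,
                         inhib_weight = f$inhib_weight,
                         sample_rate = f$sample_rate, kernel_ms = f$kernel_ms)
  }
  b <- config$bank
  bank <- build_channel_bank(
    n_channels = b$n_channels, min_width_ms = b$min_width_ms,
    max_width_ms = b$max_width_ms, spacing = b$spacing,
    window_shape = b$window_shape, transducer = b$transducer,
    adapt_strength = b$adapt_strength, adapt_sat = b$adapt_sat,
    adapt_exponent = b$adapt_exponent, adapt_rule = b$adapt_rule
  )
  list(design = design, filter = filter, bank = bank)
}
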