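#' Biphasic temporal impulse-response filter
#'
#' Constructs the model's front-end filter as the difference of two cascaded
#' exponential (gamma) stages: a fast excitatory lobe minus a slower,
#' delayed inhibitory lobe. The inhibitory lobe is rescaled so the kernel
#' integrates to zero (DC balance), which makes the filter band-pass:
#' sustained, unmodulated input produces essentially no drive. The kernel is
#' then scaled to a standard operating point: a sustained unit-amplitude
#' sinusoid at `ref_tf_hz` yields a mean rectified output of
#' `ref_drive` per millisecond. This puts different filter families
#' (see [make_lowpass_filter()]) on a common drive scale so that downstream
#' saturation constants are filter-invariant.
#'
#' @param tau_e_ms,n_e Excitatory time constant (ms) and number of stages.
#' @param tau_i_ms,n_i Inhibitory time constant (ms) and number of stages.
#' @param inhib_weight Relative weight of the inhibitory lobe before DC
#'   balancing, in `(0, 1]`. Requesting 0 with balancing on would make the
#'   kernel monophasic and is an error.
#' @param sample_rate Samples per second.
#' @param kernel_ms Kernel support (ms); the gamma lobes decay to a
#'   negligible level well within the default.
#' @param dc_balance Rescale the inhibitory lobe so the kernel sums to zero.
#' @param ref_tf_hz,ref_drive Operating-point normalization: carrier
#'   frequency used for calibration and the target mean rectified drive per
#'   ms.
#' @return An object of class `temporal_filter` with fields `kernel`,
#'   `sample_rate`, and `params`.
#' @examples
#' f <- make_biphasic_filter()
#' sum(f$kernel) / sum(abs(f$kernel)) # ~0: DC balanced
#' @export
make_biphasic_filter <- function(tau_e_ms = 8, n_e = 9,
                                 tau_i_ms = 10, n_i = 10,
                                 inhib_weight = 0.9,
                                 sample_rate = 1000,
                                 kernel_ms = 400,
                                 dc_balance = TRUE,
                                 ref_tf_hz = 10,
                                 ref_drive = 10) {
  if (tau_e_ms <= 0 || tau_i_ms <= 0) stop("time constants must be positive")
  if (inhib_weight <= 0 && dc_balance) {
    stop("inhib_weight 0 with DC balancing requested would produce a monophasic kernel")
  }
  if (inhib_weight <= 0 || inhib_weight > 1) stop("inhib_weight must be in (0, 1]")
  t_ms <- seq(0, kernel_ms, by = 1000 / sample_rate)
  gamma_stage <- function(t, tau, n) (t / tau)^(n - 1) * exp(-t / tau)
  exc <- gamma_stage(t_ms, tau_e_ms, n_e)
  inh <- gamma_stage(t_ms, tau_i_ms, n_i)
  exc <- exc / max(exc)
  inh <- inh / max(inh)
  kernel <- if (dc_balance) exc - inh * (sum(exc) / sum(inh)) else exc - inhib_weight * inh
  kernel <- kernel / max(abs(kernel))
  out <- structure(list(
    kernel = kernel,
    sample_rate = sample_rate,
    params = list(tau_e_ms = tau_e_ms, n_e = n_e, tau_i_ms = tau_i_ms,
                  n_i = n_i, inhib_weight = inhib_weight,
                  family = "biphasic", dc_balance = dc_balance)
  ), class = "temporal_filter")
  normalize_filter(out, ref_tf_hz, ref_drive)
}

#' First-order low-pass front-end filter
#'
#' An exponential-decay kernel, provided to test that the model's
#' qualitative adaptation behaviour does not hinge on the band-pass shape of
#' the default front end. Normalized to the same operating point as
#' [make_biphasic_filter()].
#'
#' @param tau_ms Decay time constant (ms).
#' @inheritParams make_biphasic_filter
#' @return A `temporal_filter`.
#' @export
make_lowpass_filter <- function(tau_ms = 20, sample_rate = 1000,
                                kernel_ms = 400, ref_tf_hz = 10,
                                ref_drive = 10) {
  if (tau_ms <= 0) stop("time constant must be positive")
  t_ms <- seq(0, kernel_ms, by = 1000 / sample_rate)
  kernel <- exp(-t_ms / tau_ms)
  out <- structure(list(
    kernel = kernel / max(kernel),
    sample_rate = sample_rate,
    params = list(tau_ms = tau_ms, family = "lowpass")
  ), class = "temporal_filter")
  normalize_filter(out, ref_tf_hz, ref_drive)
}

# Scale the kernel so a sustained unit sinusoid at ref_tf_hz gives a mean
# rectified output of ref_drive per millisecond.
normalize_filter <- function(filter, ref_tf_hz, ref_drive) {
  sr <- filter$sample_rate
  n <- 4 * sr # 4 s carrier, steady state well reached after the kernel length
  t <- (seq_len(n) - 1) / sr
  x <- sin(2 * pi * ref_tf_hz * t)
  y <- abs(convolve_causal(x, filter$kernel))
  skip <- length(filter$kernel)
  m <- mean(y[seq(skip + 1, n)])
  filter$kernel <- filter$kernel * ref_drive / m
  filter$params$ref_tf_hz <- ref_tf_hz
  filter$params$ref_drive <- ref_drive
  filter
}

# Causal linear convolution, output truncated to length(x) + length(kernel).
convolve_causal <- function(x, kernel) {
  nx <- length(x)
  nk <- length(kernel)
  if (nx == 0) return(numeric(nk))
  full <- stats::convolve(c(x, numeric(nk)), rev(kernel), type = "open")
  full[seq_len(nx + nk)]
}

#' Apply the front end to a stimulus waveform
#'
#' Convolves the waveform with the filter kernel (causal, output truncated
#' to input length plus kernel length) and rectifies. Full-wave
#' rectification keeps the drive proportional to stimulus contrast; squaring
#' is available as an energy-style alternative.
#'
#' @param waveform A [stimulus_waveform][make_test_waveform].
#' @param filter A `temporal_filter`; sample rates must match.
#' @param rectifier `"fullwave"` (`abs`) or `"square"`.
#' @return An object of class `filtered_signal` with non-negative `samples`,
#'   `sample_rate`, `source_label`, and the signed pre-rectification output
#'   in `$linear`.
#' @export
apply_frontend <- function(waveform, filter,
                           rectifier = c("fullwave", "square")) {
  rectifier <- match.arg(rectifier)
  if (waveform$sample_rate != filter$sample_rate) {
    stop(sprintf("sample rate mismatch: waveform %g Hz vs filter %g Hz",
                 waveform$sample_rate, filter$sample_rate))
  }
  lin <- convolve_causal(waveform$samples, filter$kernel)
  rect <- switch(rectifier, fullwave = abs(lin), square = lin^2)
  structure(list(
    samples = rect,
    linear = lin,
    sample_rate = waveform$sample_rate,
    source_label = waveform$label,
    rectifier = rectifier
  ), class = "filtered_signal")
}

#' @export
print.temporal_filter <- function(x, ...) {
  cat(sprintf("<temporal_filter> %s, %d taps @ %g Hz\n",
              x$params$family, length(x$kernel), x$sample_rate))
  invisible(x)
}

#' @export
as.data.frame.temporal_filter <- function(x, ...) {
  data.frame(time_ms = (seq_along(x$kernel) - 1) * 1000 / x$sample_rate,
             amplitude = x$kernel)
}
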