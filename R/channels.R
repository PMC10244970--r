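#' Build a bank of duration-tuned pooling mechanisms
#'
#' The model represents duration with a population of mechanisms that pool
#' rectified front-end drive over temporal windows of different extents
#' (their full width at half height, FWHH, is the channel's duration label).
#' Widths are log-spaced by default. Each channel carries a multiplicative
#' gain in `[0, 1]`, initialized to 1 and reduced by adaptation.
#'
#' The bank also holds the non-linear transducer of the readout stage,
#' \deqn{R_i = (g_i L_i)^p / (z + w (g_N L_N)^q),}
#' where `L` are the pooled linear drives, `g` the gains, and channel `N`
#' the widest mechanism (divisive suppression from the largest mechanism),
#' and the parameters of the adaptation stage: the drive each channel takes
#' from an adaptor is passed through a saturating (Hill) non-linearity
#' `A_i = L_i^e / (za + L_i^e)` before the proportional gain rule (see
#' [adapt_gains()]). The saturation concentrates adaptation's differential
#' effect at the narrow end of the bank, which is what makes compression by
#' a sustained flicker adaptor proportionally strongest for short targets.
#'
#' @param n_channels Number of mechanisms (at least 8; fewer would make the
#'   neighbour-difference readout too coarse).
#' @param min_width_ms,max_width_ms Narrowest and widest FWHH (ms).
#' @param spacing `"log"` (geometric, default) or `"linear"`.
#' @param window_shape `"raisedcos"` (default) or `"rect"`. Raised-cosine
#'   windows rise from stimulus onset, peak at `t = FWHH` and return to zero
#'   at `2 * FWHH`, giving genuine duration tuning; rectangular windows are
#'   pure integrators.
#' @param transducer Named list with excitatory exponent `p`, suppressive
#'   exponent `q` (`p > q >= 1`), saturation constant `z > 0`, and
#'   suppression weight `w`.
#' @param adapt_strength Adaptation strength `alpha` in `[0, 1)`.
#' @param adapt_sat Half-saturation constant of the adaptation stage (drive
#'   units; the front-end normalization of [make_biphasic_filter()] makes
#'   this filter-invariant).
#' @param adapt_exponent Hill exponent of the adaptation stage.
#' @param adapt_rule `"linear"` (`g = 1 - alpha * A`) or `"divisive"`
#'   (`g = 1 / (1 + alpha * A)`).
#' @return An object of class `channel_bank`.
#' @examples
#' bank <- build_channel_bank(9, 100, 25600)
#' bank$widths_ms # exact octave steps
#' @export
build_channel_bank <- function(n_channels = 61,
                               min_width_ms = 50,
                               max_width_ms = 4000,
                               spacing = c("log", "linear"),
                               window_shape = c("raisedcos", "rect"),
                               transducer = list(p = 2.4, q = 2, z = 1, w = 1),
                               adapt_strength = 0.6,
                               adapt_sat = 2,
                               adapt_exponent = 2,
                               adapt_rule = c("linear", "divisive")) {
  spacing <- match.arg(spacing)
  window_shape <- match.arg(window_shape)
  adapt_rule <- match.arg(adapt_rule)
  if (n_channels < 8) {
    stop("need at least 8 channels for a usable derivative readout")
  }
  if (min_width_ms >= max_width_ms) stop("min_width_ms must be < max_width_ms")
  if (adapt_strength < 0 || adapt_strength >= 1) {
    stop("adapt_strength must be in [0, 1)")
  }
  td <- utils::modifyList(list(p = 2.4, q = 2, z = 1, w = 1), transducer)
  if (!(td$p > td$q && td$q >= 1)) stop("transducer requires p > q >= 1")
  if (td$z <= 0) stop("transducer saturation constant z must be positive")
  widths <- switch(spacing,
    log = exp(seq(log(min_width_ms), log(max_width_ms), length.out = n_channels)),
    linear = seq(min_width_ms, max_width_ms, length.out = n_channels)
  )
  structure(list(
    widths_ms = widths,
    window_shape = window_shape,
    gains = rep(1, n_channels),
    transducer = td,
    adapt_strength = adapt_strength,
    adapt_sat = adapt_sat,
    adapt_exponent = adapt_exponent,
    adapt_rule = adapt_rule
  ), class = "channel_bank")
}

#' @export
print.channel_bank <- function(x, ...) {
  cat(sprintf(
    "<channel_bank> %d %s channels, FWHH %.0f-%.0f ms, p=%.2g q=%.2g z=%.2g, alpha=%.2g%s\n",
    length(x$widths_ms), x$window_shape, min(x$widths_ms), max(x$widths_ms),
    x$transducer$p, x$transducer$q, x$transducer$z, x$adapt_strength,
    if (all(x$gains == 1)) "" else " (adapted)"
  ))
  invisible(x)
}

# Pooling window of one channel, sampled at sample_rate, unit peak,
# anchored at stimulus onset. Both shapes have area = FWHH (in ms).
channel_window <- function(width_ms, shape, sample_rate, n_samples) {
  t_ms <- (seq_len(n_samples) - 1) * 1000 / sample_rate
  if (shape == "rect") {
    as.numeric(t_ms < width_ms)
  } else {
    w <- numeric(n_samples)
    idx <- t_ms < 2 * width_ms
    w[idx] <- 0.5 * (1 - cos(pi * t_ms[idx] / width_ms))
    w
  }
}

#' Pooled linear drive of each channel
#'
#' Integrates a rectified front-end signal against each channel's pooling
#' window (anchored at stimulus onset): `L_i = sum_t s(t) w_i(t) / rate`.
#' For a non-negative signal and rectangular windows, `L` is non-decreasing
#' across widths.
#'
#' @param signal A [filtered_signal][apply_frontend], or a non-negative
#'   numeric vector (then `sample_rate` must be given).
#' @param bank A [channel_bank][build_channel_bank].
#' @param sample_rate Samples per second, if `signal` is a bare vector.
#' @return Numeric vector of per-channel drives (one per width).
#' @export
channel_drive <- function(signal, bank, sample_rate = NULL) {
  if (inherits(signal, "filtered_signal")) {
    s <- signal$samples
    sr <- signal$sample_rate
  } else {
    s <- as.numeric(signal)
    sr <- sample_rate
    if (is.null(sr)) stop("sample_rate required for a bare numeric signal")
  }
  n <- length(s)
  vapply(bank$widths_ms, function(w) {
    nw <- if (bank$window_shape == "rect") {
      min(n, ceiling(w / 1000 * sr))
    } else {
      min(n, ceiling(2 * w / 1000 * sr))
    }
    if (nw == 0 || n == 0) return(0)
    win <- channel_window(w, bank$window_shape, sr, nw)
    sum(s[seq_len(nw)] * win) / sr
  }, numeric(1))
}

# Steady-state drive of a sustained stimulus with mean rectified front-end
# level m: window area (= FWHH ms) times level. Used for long adaptors.
sustained_drive <- function(mean_level, bank) {
  mean_level * bank$widths_ms / 1000
}

new_population_response <- function(R, widths_ms, stimulus_label) {
  structure(list(R = R, widths_ms = widths_ms, stimulus_label = stimulus_label),
            class = "population_response")
}

#' Non-linear transduction with divisive suppression
#'
#' Applies the readout transducer to the pooled drives:
#' `R_i = (g_i L_i)^p / (z + w (g_N L_N)^q)` where `N` indexes the widest
#' mechanism. Across widths the transduced profile to a fixed-duration
#' target rises and saturates, and the neighbour-difference derivative peaks
#' near the channel whose preferred duration matches the stimulus.
#'
#' @param L Per-channel linear drives (non-negative), as from
#'   [channel_drive()].
#' @param bank A [channel_bank][build_channel_bank] (its gains are applied).
#' @param stimulus_label Free-text label stored in the result.
#' @return A `population_response` with non-negative `R`.
#' @export
transduce <- function(L, bank, stimulus_label = "") {
  td <- bank$transducer
  if (td$z <= 0) stop("transducer saturation constant z must be positive")
  if (any(L < 0)) stop("drives must be non-negative")
  gl <- bank$gains * L
  N <- length(gl)
  R <- gl^td$p / (td$z + td$w * gl[N]^td$q)
  new_population_response(R, bank$widths_ms, stimulus_label)
}

#' Adaptation-stage response to an adaptor
#'
#' Each channel's gain loss under adaptation is driven not by the raw
#' pooled drive but by a saturating (Hill) transform of it,
#' `A_i = L_i^e / (za + L_i^e)`: gain control saturates once a channel is
#' strongly driven. Event-like adaptors (a fixed-duration target) supply
#' their onset-anchored pooled drive; sustained adaptors (long flicker)
#' supply their steady-state drive.
#'
#' @param L Per-channel linear drives of the adaptor.
#' @inheritParams transduce
#' @return A `population_response` holding the saturated adaptation drives.
#' @export
adaptation_response <- function(L, bank, stimulus_label = "adaptor") {
  if (any(L < 0)) stop("drives must be non-negative")
  e <- bank$adapt_exponent
  A <- L^e / (bank$adapt_sat + L^e)
  new_population_response(A, bank$widths_ms, stimulus_label)
}

#' Adapt channel gains in proportion to the adaptor response
#'
#' Implements gain-control adaptation: each mechanism's gain is reduced in
#' proportion to its (saturated) response to the adapting stimulus,
#' normalized by the maximally responding mechanism. Under the default
#' linear rule `g_i = 1 - alpha * A_i / max(A)`, so gains lie in
#' `[1 - alpha, 1]` and the maximally driven channel ends at exactly
#' `1 - alpha`. A divisive variant `g_i = 1 / (1 + alpha * A_i / max(A))`
#' is selected by the bank's `adapt_rule`.
#'
#' If the adaptor produced no response at all the gains are left unchanged
#' (a documented no-op, not an error).
#'
#' @param bank An unadapted [channel_bank][build_channel_bank] (gains 1).
#' @param adaptor_pop A `population_response` from [adaptation_response()]
#'   computed on the same bank at unit gains.
#' @return A new `channel_bank` with adapted gains; the input is unchanged.
#' @export
adapt_gains <- function(bank, adaptor_pop) {
  if (length(adaptor_pop$R) != length(bank$widths_ms)) {
    stop("adaptor response and bank have different numbers of channels")
  }
  mx <- max(adaptor_pop$R)
  if (mx <= 0) return(bank)
  Ahat <- adaptor_pop$R / mx
  a <- bank$adapt_strength
  bank$gains <- switch(bank$adapt_rule,
    linear = 1 - a * Ahat,
    divisive = 1 / (1 + a * Ahat)
  )
  bank
}

#' Derivative-peak readout of a population response
#'
#' The model reads out duration from where the population profile rises
#' most steeply across widths: the derivative is the difference between
#' each mechanism and its wider neighbour, `d_i = R_{i+1} - R_i`, plotted
#' at the geometric mean of the two widths. The peak is refined by
#' three-point parabolic interpolation in log-width (ties break toward the
#' narrower width because the first maximum is taken); a centroid readout
#' over the positive part of the derivative is available as an alternative.
#'
#' @param pop A `population_response` with at least 3 channels.
#' @param method `"parabolic"` (default) or `"centroid"`.
#' @return An object of class `duration_readout` with `peak_width_ms`,
#'   `derivative`, and `derivative_width_ms`.
#' @export
readout_peak <- function(pop, method = c("parabolic", "centroid")) {
  method <- match.arg(method)
  R <- pop$R
  widths <- pop$widths_ms
  if (length(R) < 3) stop("need at least 3 channels for a derivative readout")
  d <- diff(R)
  gm <- sqrt(widths[-1] * widths[-length(widths)])
  if (all(d == 0)) stop("no peak: population response is flat")
  peak <- if (method == "centroid") {
    pos <- pmax(d, 0)
    if (all(pos == 0)) stop("no peak: derivative has no positive part")
    exp(sum(pos * log(gm)) / sum(pos))
  } else {
    i <- which.max(d)
    if (i == 1 || i == length(d)) {
      gm[i]
    } else {
      x <- log(gm[(i - 1):(i + 1)])
      y <- d[(i - 1):(i + 1)]
      a2 <- (y[1] - 2 * y[2] + y[3]) / 2
      b <- (y[3] - y[1]) / 2
      if (a2 >= 0) gm[i] else exp(x[2] - b / (2 * a2) * (x[3] - x[2]))
    }
  }
  structure(list(peak_width_ms = peak, derivative = d,
                 derivative_width_ms = gm, method = method),
            class = "duration_readout")
}

# Unadapted population response of a 10 Hz test of a given duration.
test_response <- function(duration_ms, bank, filter, test_tf_hz = 10,
                          test_contrast = 0.8, rectifier = "fullwave") {
  wf <- make_test_waveform(duration_ms, test_tf_hz, test_contrast,
                           filter$sample_rate)
  sig <- apply_frontend(wf, filter, rectifier)
  channel_drive(sig, bank)
}

#' Calibrate the baseline duration mapping
#'
#' Runs the unadapted model over a grid of physical durations, records the
#' readout peak width for each, and smooths the curve with isotonic
#' regression in log-log coordinates. (Raw peak positions carry small
#' "wiggles" at brief durations from the interaction between carrier phase
#' and the stimulus envelope; the isotonic fit removes them.) The result is
#' an invertible monotone map between physical duration and peak width used
#' by [predict_perceived_duration()] to express adapted readouts as
#' physical-duration equivalents.
#'
#' @param bank An unadapted [channel_bank][build_channel_bank].
#' @param filter A [temporal_filter][make_biphasic_filter].
#' @param duration_grid_ms Calibration grid (ms). The default extends past
#'   the durations usually probed (300-2000 ms) so that adapted readouts
#'   stay decodable.
#' @param test_tf_hz,test_contrast Test carrier parameters.
#' @param readout Readout method passed to [readout_peak()].
#' @param max_rel_dev Error if any raw peak deviates from the isotonic fit
#'   by more than this relative amount (a misconfigured bank).
#' @return An object of class `baseline_mapping`.
#' @export
calibrate_baseline <- function(bank, filter,
                               duration_grid_ms = seq(100, 3200, by = 50),
                               test_tf_hz = 10, test_contrast = 0.8,
                               readout = "parabolic",
                               max_rel_dev = 0.2) {
  if (any(bank$gains != 1)) {
    stop("calibrate_baseline requires an unadapted bank (all gains 1)")
  }
  peaks <- vapply(duration_grid_ms, function(d) {
    L <- test_response(d, bank, filter, test_tf_hz, test_contrast)
    readout_peak(transduce(L, bank), method = readout)$peak_width_ms
  }, numeric(1))
  iso <- stats::isoreg(log(duration_grid_ms), log(peaks))
  smooth_log_width <- iso$yf
  if (max(abs(exp(smooth_log_width) / peaks - 1)) > max_rel_dev) {
    stop("baseline peak-width curve is non-monotone beyond tolerance; bank misconfigured")
  }
  # strictify flat spans minutely so the inverse lookup is well defined
  smooth_log_width <- smooth_log_width +
    seq_along(smooth_log_width) * 1e-9
  structure(list(
    grid_ms = duration_grid_ms,
    peak_width_ms = peaks,
    smooth_log_width = smooth_log_width,
    test_tf_hz = test_tf_hz,
    test_contrast = test_contrast,
    readout = readout
  ), class = "baseline_mapping")
}

#' Look up the unadapted peak width for a physical duration
#'
#' @param mapping A [baseline_mapping][calibrate_baseline].
#' @param duration_ms Physical duration(s), within the calibration grid.
#' @return Peak width(s) in ms (smoothed baseline).
#' @export
baseline_lookup <- function(mapping, duration_ms) {
  rng <- range(mapping$grid_ms)
  if (any(duration_ms < rng[1] | duration_ms > rng[2])) {
    stop(sprintf("duration outside calibration grid [%g, %g] ms", rng[1], rng[2]))
  }
  exp(stats::approx(log(mapping$grid_ms), mapping$smooth_log_width,
                    xout = log(duration_ms), ties = "ordered")$y)
}

#' Decode a peak width to a physical-duration equivalent
#'
#' Inverts the baseline mapping by linear interpolation in log-duration.
#'
#' @param mapping A [baseline_mapping][calibrate_baseline].
#' @param peak_width_ms Readout peak width(s) in ms.
#' @return Decoded duration(s) in ms.
#' @export
decode_duration <- function(mapping, peak_width_ms) {
  lw <- log(peak_width_ms)
  rng <- range(mapping$smooth_log_width)
  if (any(lw < rng[1] | lw > rng[2])) {
    bad <- peak_width_ms[lw < rng[1] | lw > rng[2]]
    stop(sprintf(
      "peak width %.3g ms outside the decodable range [%.3g, %.3g] ms; extend the calibration grid",
      bad[1], exp(rng[1]), exp(rng[2])
    ))
  }
  exp(stats::approx(mapping$smooth_log_width, log(mapping$grid_ms),
                    xout = lw, ties = "ordered")$y)
}

#' Adaptor specifications
#'
#' `fixed_adaptor()` describes repeated exposure to a test-like target of a
#' fixed duration (the duration-adaptation paradigm); `flicker_adaptor()`
#' describes prolonged exposure to the mixed-frequency flicker/drift
#' adaptor (the motion-adaptation paradigm). The fixed adaptor enters the
#' model as an onset-anchored event; the flicker adaptor through its
#' steady-state drive (mean rectified front-end level over a long epoch
#' times each channel's window area), reflecting tens of seconds of
#' adaptation with randomized segment order.
#'
#' @param duration_ms Event duration of the fixed adaptor (ms).
#' @param tf_hz Carrier frequency of the fixed adaptor (Hz).
#' @param contrast Adaptor contrast.
#' @param tf_pair_hz The two flicker frequencies (Hz).
#' @param segment_ms Flicker segment duration (ms).
#' @param epoch_s Epoch length used to measure the steady-state level (s).
#' @return An `adaptor_spec` object.
#' @export
fixed_adaptor <- function(duration_ms = 800, tf_hz = 10, contrast = 0.8) {
  structure(list(type = "fixed", duration_ms = duration_ms, tf_hz = tf_hz,
                 contrast = contrast), class = "adaptor_spec")
}

#' @rdname fixed_adaptor
#' @export
flicker_adaptor <- function(tf_pair_hz = c(5, 20), contrast = 0.5,
                            segment_ms = 500, epoch_s = 8) {
  structure(list(type = "flicker", tf_pair_hz = tf_pair_hz,
                 contrast = contrast, segment_ms = segment_ms,
                 epoch_s = epoch_s), class = "adaptor_spec")
}

# Adaptor drives for the adaptation stage.
adaptor_drive <- function(adaptor, bank, filter, rectifier = "fullwave") {
  sr <- filter$sample_rate
  if (adaptor$type == "fixed") {
    wf <- make_test_waveform(adaptor$duration_ms, adaptor$tf_hz,
                             adaptor$contrast, sr)
    channel_drive(apply_frontend(wf, filter, rectifier), bank)
  } else {
    n_seg <- round(adaptor$epoch_s * 1000 / adaptor$segment_ms)
    seg_f <- rep(adaptor$tf_pair_hz, length.out = n_seg)
    n_per <- round(adaptor$segment_ms / 1000 * sr)
    t <- (seq_len(n_per) - 1) / sr
    samples <- unlist(lapply(seg_f, function(f) {
      adaptor$contrast * sin(2 * pi * f * t)
    }))
    wf <- new_stimulus_waveform(samples, sr, adaptor$epoch_s * 1000, "flicker epoch")
    y <- apply_frontend(wf, filter, rectifier)$samples
    skip <- n_per # one segment's worth of onset transient
    level <- mean(y[seq(skip + 1, length(samples) - skip)])
    sustained_drive(level, bank)
  }
}

#' Adapt a bank to an adaptor specification
#'
#' Convenience wrapper: computes the adaptor's drives, passes them through
#' the saturating adaptation stage, and applies the gain rule.
#'
#' @param bank An unadapted [channel_bank][build_channel_bank].
#' @param adaptor An [adaptor_spec][fixed_adaptor], or `NULL` for no
#'   adaptation.
#' @param filter A [temporal_filter][make_biphasic_filter].
#' @return A `channel_bank` with adapted gains.
#' @export
adapt_bank <- function(bank, adaptor, filter) {
  if (is.null(adaptor)) return(bank)
  L <- adaptor_drive(adaptor, bank, filter)
  adapt_gains(bank, adaptation_response(L, bank))
}

#' Predict perceived duration
#'
#' Runs the (possibly adapted) model on a 10 Hz target of each requested
#' duration, reads out the derivative peak, and inverts the baseline
#' mapping to express the result as a physical-duration equivalent.
#' Without an adaptor the prediction is the identity (up to interpolation
#' error of the calibration).
#'
#' @param duration_ms Target duration(s) in ms.
#' @param adaptor An [adaptor_spec][fixed_adaptor] or `NULL`.
#' @param bank An unadapted [channel_bank][build_channel_bank].
#' @param filter A [temporal_filter][make_biphasic_filter].
#' @param mapping A [baseline_mapping][calibrate_baseline] for the same bank
#'   and filter.
#' @return Decoded duration(s) in ms.
#' @examples
#' \donttest{
#' bank <- build_channel_bank()
#' filt <- make_biphasic_filter()
#' mapping <- calibrate_baseline(bank, filt)
#' predict_perceived_duration(600, flicker_adaptor(), bank, filt, mapping)
#' }
#' @export
predict_perceived_duration <- function(duration_ms, adaptor = NULL,
                                       bank, filter, mapping) {
  adapted <- adapt_bank(bank, adaptor, filter)
  vapply(duration_ms, function(d) {
    L <- test_response(d, bank, filter, mapping$test_tf_hz, mapping$test_contrast)
    pk <- readout_peak(transduce(L, adapted), method = mapping$readout)
    decode_duration(mapping, pk$peak_width_ms)
  }, numeric(1))
}

#' Predicted change in perceived duration after adaptation
#'
#' @inheritParams predict_perceived_duration
#' @return Percent change `100 * (decoded - duration) / duration`, one value
#'   per duration. Negative values are perceived compression.
#' @export
predict_adaptation_effect <- function(duration_ms, adaptor,
                                      bank, filter, mapping) {
  dec <- predict_perceived_duration(duration_ms, adaptor, bank, filter, mapping)
  100 * (dec - duration_ms) / duration_ms
}
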