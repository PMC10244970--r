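#' Experiment design constants
#'
#' Returns the design of the adaptation experiment the analysis and the
#' synthetic-data generator assume: two standard durations (a sub-second
#' 600 ms and a supra-second 1200 ms), seven comparison durations expressed
#' as fractions of the standard, at least 20 repetitions per comparison
#' level, a 50%-contrast adaptor alternating between two drift/flicker
#' frequencies in 500 ms segments, and 80%-contrast 10 Hz test stimuli.
#'
#' @param standards_ms Standard durations in milliseconds.
#' @param comparison_fractions Comparison durations as fractions of the
#'   standard. Must be sorted ascending and include 1 (the objectively equal
#'   comparison).
#' @param min_reps Minimum repetitions per comparison level and cell.
#' @param adaptor_contrast,test_contrast Michelson contrasts, in `[0, 1]`.
#' @param test_tf_hz Temporal frequency of the test carrier (Hz).
#' @param adaptor_tf_hz The two adaptor frequencies (Hz); each occupies
#'   exactly half of the total adaptation time.
#' @param segment_ms Duration of one adaptor segment before the drift
#'   direction/frequency changes.
#' @param initial_adapt_s,topup_adapt_s Initial and top-up adaptation
#'   durations in seconds.
#' @param isi_ms Inter-stimulus interval (ms).
#'
#' @return An object of class `experiment_design` (a named list).
#' @examples
#' design <- experiment_design()
#' design$comparison_fractions
#' comparison_levels_pct(design)
#' @export
experiment_design <- function(standards_ms = c(600, 1200),
                              comparison_fractions = c(1 / 3, 2 / 3, 5 / 6, 1, 7 / 6, 4 / 3, 5 / 3),
                              min_reps = 20,
                              adaptor_contrast = 0.5,
                              test_contrast = 0.8,
                              test_tf_hz = 10,
                              adaptor_tf_hz = c(5, 20),
                              segment_ms = 500,
                              initial_adapt_s = 32,
                              topup_adapt_s = 8,
                              isi_ms = 500) {
  if (is.unsorted(comparison_fractions, strictly = TRUE)) {
    stop("comparison_fractions must be strictly ascending")
  }
  if (!any(abs(comparison_fractions - 1) < 1e-12)) {
    stop("comparison_fractions must include 1 (the equal comparison)")
  }
  if (length(adaptor_tf_hz) != 2) {
    stop("adaptor_tf_hz must contain exactly two frequencies")
  }
  structure(list(
    standards_ms = standards_ms,
    comparison_fractions = comparison_fractions,
    min_reps = min_reps,
    adaptor_contrast = adaptor_contrast,
    test_contrast = test_contrast,
    test_tf_hz = test_tf_hz,
    adaptor_tf_hz = adaptor_tf_hz,
    segment_ms = segment_ms,
    initial_adapt_s = initial_adapt_s,
    topup_adapt_s = topup_adapt_s,
    isi_ms = isi_ms
  ), class = "experiment_design")
}

#' Comparison levels as signed percent of the standard
#'
#' Converts the design's comparison fractions to signed percentage
#' differences relative to the standard duration (the unit all fits and
#' summaries use), e.g. fraction 1/3 becomes -66.67.
#'
#' @param design An [experiment_design()].
#' @return Numeric vector of signed percent differences.
#' @export
comparison_levels_pct <- function(design = experiment_design()) {
  100 * (design$comparison_fractions - 1)
}

#' Convert drift speed to temporal frequency
#'
#' For a drifting grating, temporal frequency is the product of drift speed
#' and spatial frequency. A 1 cycle/degree grating drifting at 10 deg/s
#' modulates local luminance at 10 Hz, which is why a one-dimensional
#' temporal model can stand in for the drifting stimulus.
#'
#' @param speed_deg_per_s Drift speed in degrees of visual angle per second.
#' @param spatial_freq_cpd Spatial frequency in cycles per degree.
#' @return Temporal frequency in Hz.
#' @examples
#' speed_to_temporal_frequency(10, 1) # 10 Hz test
#' speed_to_temporal_frequency(5, 1)  # slow adaptor component
#' @export
speed_to_temporal_frequency <- function(speed_deg_per_s, spatial_freq_cpd) {
  if (any(speed_deg_per_s <= 0) || any(spatial_freq_cpd <= 0)) {
    stop("speed and spatial frequency must be positive")
  }
  speed_deg_per_s * spatial_freq_cpd
}

new_stimulus_waveform <- function(samples, sample_rate, duration_ms, label) {
  structure(list(
    samples = samples,
    sample_rate = sample_rate,
    duration_ms = duration_ms,
    label = label
  ), class = "stimulus_waveform")
}

#' Sinusoidal test waveform
#'
#' Builds the one-dimensional temporal modulation signal of a test stimulus:
#' a sinusoidal carrier at `tf_hz` inside a rectangular envelope of
#' `duration_ms`, starting at phase `phase` at onset and zero outside the
#' envelope. Amplitude equals the Michelson contrast of the grating it
#' stands in for.
#'
#' @param duration_ms Envelope duration (ms), may be 0.
#' @param tf_hz Carrier temporal frequency (Hz).
#' @param contrast Peak amplitude in `[0, 1]`.
#' @param sample_rate Samples per second; must be at least `4 * tf_hz`.
#' @param phase Carrier phase at onset (radians). Held at 0 by default so
#'   that carrier-phase/envelope interactions are a controlled constant.
#' @return A `stimulus_waveform`.
#' @examples
#' w <- make_test_waveform(600, 10, 0.8)
#' length(w$samples) # 600 samples at 1 kHz
#' @export
make_test_waveform <- function(duration_ms, tf_hz, contrast = 0.8,
                               sample_rate = 1000, phase = 0) {
  if (duration_ms < 0) stop("duration_ms must be >= 0")
  if (contrast < 0 || contrast > 1) stop("contrast must be in [0, 1]")
  if (sample_rate < 4 * tf_hz) {
    stop(sprintf(
      "sample_rate %g Hz undersamples a %g Hz carrier (need >= 4x carrier; Nyquist violation)",
      sample_rate, tf_hz
    ))
  }
  n <- round(duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  samples <- contrast * sin(2 * pi * tf_hz * t + phase)
  new_stimulus_waveform(samples, sample_rate, duration_ms,
                        sprintf("test %g ms %g Hz", duration_ms, tf_hz))
}

#' Frequency-alternating adaptor waveform
#'
#' Builds the modulation signal of the mixed-frequency adaptor: a
#' concatenation of fixed-length segments whose carrier alternates between
#' two temporal frequencies such that each frequency occupies exactly half
#' of the total duration, with the segment order shuffled under
#' `order_seed`. Carrier phase is continuous across segment boundaries (a
#' drifting grating changing speed does not jump in phase), so a degenerate
#' equal-frequency pair yields a pure sinusoid.
#'
#' @param total_s Total duration in seconds; `total_s * 1000` must be a
#'   multiple of `segment_ms` and the segment count must be even.
#' @param segment_ms Segment duration (ms).
#' @param tf_pair_hz The two carrier frequencies (Hz).
#' @param contrast Peak amplitude in `[0, 1]`.
#' @param sample_rate Samples per second.
#' @param order_seed Integer seed for the segment-order shuffle.
#' @return A `stimulus_waveform` with attribute `segment_tf_hz`, the
#'   per-segment frequency sequence actually used.
#' @examples
#' a <- make_adaptor_waveform(8, 500, c(5, 20), 0.5, order_seed = 1)
#' table(attr(a, "segment_tf_hz")) # 8 segments of each frequency
#' @export
make_adaptor_waveform <- function(total_s, segment_ms = 500,
                                  tf_pair_hz = c(5, 20), contrast = 0.5,
                                  sample_rate = 1000, order_seed = 1) {
  total_ms <- total_s * 1000
  if (abs(total_ms / segment_ms - round(total_ms / segment_ms)) > 1e-9) {
    stop("total duration must be a multiple of segment_ms")
  }
  if (length(tf_pair_hz) != 2) stop("tf_pair_hz must have two entries")
  n_seg <- round(total_ms / segment_ms)
  if (n_seg %% 2 != 0) {
    stop("odd segment count: cannot split the two frequencies 50-50")
  }
  seg_f <- rep(tf_pair_hz, each = n_seg / 2)
  perm <- with_local_seed(order_seed, sample.int(n_seg))
  seg_f <- seg_f[perm]
  n_per_seg <- round(segment_ms / 1000 * sample_rate)
  phase <- 0
  dt <- 1 / sample_rate
  samples <- numeric(n_seg * n_per_seg)
  idx <- 1
  for (f in seg_f) {
    ph <- phase + 2 * pi * f * dt * (seq_len(n_per_seg) - 1)
    samples[idx:(idx + n_per_seg - 1)] <- contrast * sin(ph)
    phase <- phase + 2 * pi * f * dt * n_per_seg
    idx <- idx + n_per_seg
  }
  out <- new_stimulus_waveform(samples, sample_rate, total_ms,
                               sprintf("adaptor %g s %s Hz", total_s,
                                       paste(tf_pair_hz, collapse = "/")))
  attr(out, "segment_tf_hz") <- seg_f
  out
}

#' @export
print.stimulus_waveform <- function(x, ...) {
  cat(sprintf("<stimulus_waveform> %s: %d samples @ %g Hz (%g ms)\n",
              x$label, length(x$samples), x$sample_rate, x$duration_ms))
  invisible(x)
}

#' @export
as.data.frame.stimulus_waveform <- function(x, ...) {
  data.frame(time_s = (seq_along(x$samples) - 1) / x$sample_rate,
             amplitude = x$samples)
}

#' Write a waveform to CSV
#'
#' Exports `(time_s, amplitude)` rows for inspection or plotting.
#'
#' @param waveform A `stimulus_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(as.data.frame(waveform), path, row.names = FALSE)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
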