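#' Butterworth conditioning-chain specification
#'
#' The chain applied to the continuous EMG: a low-pass, a high-pass, and a
#' comb of three narrow band-stop (notch) filters removing mains interference
#' and its first two harmonics, all Butterworth. A separate low-pass cutoff is
#' used later for envelope smoothing of the rectified signal. Only the filter
#' family and cutoffs are fixed by the analysis convention; order and phase
#' behaviour are configurable, with zero-phase (forward-backward) application
#' as the default so the envelope is not delayed relative to the movie scenes.
#'
#' @param low_pass,high_pass band edges in Hz of the analysis band.
#' @param notch_bands list of (low, high) Hz pairs to reject.
#' @param envelope_low_pass cutoff in Hz of the envelope smoothing filter.
#' @param order filter order of the low- and high-pass stages.
#' @param notch_order filter order of each band-stop stage.
#' @param zero_phase logical; apply each filter forward and backward
#'   (squaring its magnitude response, doubling the effective order) instead
#'   of a single causal pass.
#' @return an object of class `femg_filter_spec`.
#' @export
filter_spec <- function(low_pass = 400, high_pass = 30,
                        notch_bands = list(c(49.9, 50.1), c(99, 101), c(149, 151)),
                        envelope_low_pass = 20,
                        order = 4, notch_order = 2,
                        zero_phase = TRUE) {
  assert_scalar_number(low_pass, "low_pass", lower = 0)
  assert_scalar_number(high_pass, "high_pass", lower = 0)
  if (high_pass >= low_pass) stopf("`high_pass` must be below `low_pass`")
  bands <- do.call(rbind, notch_bands)
  if (any(bands[, 1] >= bands[, 2])) stopf("notch bands must be increasing pairs")
  o <- order(bands[, 1])
  if (any(bands[o, 2][-nrow(bands)] > bands[o, 1][-1])) {
    stopf("notch bands must be disjoint")
  }
  structure(list(low_pass = low_pass, high_pass = high_pass,
                 notch_bands = notch_bands,
                 envelope_low_pass = envelope_low_pass,
                 order = order, notch_order = notch_order,
                 zero_phase = zero_phase),
            class = "femg_filter_spec")
}

# Single causal IIR pass (transfer-function form), compiled.
iir_filter <- function(b, a, x) {
  iir_filter_cpp(b / a[1], a / a[1], x)
}

# Zero-phase filtering with odd (point-symmetric) reflection padding at both
# ends, so constant offsets and slow trends do not produce edge transients.
zero_phase_filter <- function(b, a, x, pad = NULL) {
  pad <- min(length(x) - 1L, pad %||% max(3L * (length(a) + length(b)), 256L))
  zero_phase_cpp(b, a, x, as.integer(pad))
}

apply_one_filter <- function(x, flt, zero_phase, pad = NULL) {
  if (zero_phase) zero_phase_filter(flt$b, flt$a, x, pad = pad)
  else iir_filter(flt$b, flt$a, x)
}

#' Apply the band-filtering cascade to a recording or signal vector
#'
#' Applies low-pass, high-pass, and the notch comb, in that order, to the
#' continuous signal. The cascade is linear and time-invariant, so the stage
#' order only matters up to numerical round-off. Length is preserved.
#'
#' @param x a `femg_recording` or a numeric vector.
#' @param spec a [filter_spec()].
#' @param sampling_rate required when `x` is a bare vector.
#' @return object of the same shape as `x`, filtered.
#' @export
apply_filter_chain <- function(x, spec = filter_spec(), sampling_rate = NULL) {
  if (inherits(x, "femg_recording")) {
    out <- x
    out$samples <- apply(x$samples, 2, apply_filter_chain, spec = spec,
                         sampling_rate = x$sampling_rate)
    dimnames(out$samples) <- dimnames(x$samples)
    return(out)
  }
  rate <- sampling_rate
  if (is.null(rate)) stopf("`sampling_rate` is required for vector input")
  nyq <- rate / 2
  if (spec$low_pass >= nyq) {
    stopf(paste("low-pass cutoff (%g Hz) is at or above the Nyquist frequency",
                "(%g Hz); lower the cutoff or increase the sampling rate"),
          spec$low_pass, nyq)
  }
  if (anyNA(x)) stopf("input signal contains NA/NaN samples")

  pad <- ms_to_samples(1000, rate)  # 1 s reflection padding
  y <- apply_one_filter(x, signal::butter(spec$order, spec$low_pass / nyq, "low"),
                        spec$zero_phase, pad)
  y <- apply_one_filter(y, signal::butter(spec$order, spec$high_pass / nyq, "high"),
                        spec$zero_phase, pad)
  for (band in spec$notch_bands) {
    if (band[2] >= nyq) stopf("notch band (%g-%g Hz) reaches the Nyquist frequency",
                              band[1], band[2])
    y <- apply_one_filter(y, signal::butter(spec$notch_order, band / nyq, "stop"),
                          spec$zero_phase, pad)
  }
  y
}

#' Extract the rectified low-frequency envelope of a filtered epoch
#'
#' Rectification (absolute value) followed by low-pass smoothing at the
#' envelope cutoff. The result is nonnegative up to filter ringing. Reflection
#' padding is applied at the edges in zero-phase mode.
#'
#' @param x numeric vector (an already band-filtered epoch) or matrix with
#'   epochs in rows.
#' @param spec a [filter_spec()].
#' @param sampling_rate sampling rate in Hz.
#' @return envelope of the same shape as `x`.
#' @export
extract_envelope <- function(x, spec = filter_spec(), sampling_rate) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, extract_envelope, spec = spec,
                   sampling_rate = sampling_rate)))
  }
  min_len <- 3 * sampling_rate / spec$envelope_low_pass
  if (length(x) < min_len) {
    stopf("epoch too short for envelope extraction (need >= %d samples)",
          ceiling(min_len))
  }
  flt <- signal::butter(spec$order, spec$envelope_low_pass / (sampling_rate / 2),
                        "low")
  apply_one_filter(abs(x), flt, spec$zero_phase,
                   pad = ms_to_samples(500, sampling_rate))
}
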