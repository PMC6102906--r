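#' Causal Butterworth band-pass filter
#'
#' Zero-state causal filtering (the online contract: the output at time t
#' depends only on samples at or before t), applied channel-wise. The design
#' is a Butterworth band-pass (4 poles per band edge), which attenuates a
#' sinusoid one octave outside the band by more than 20 dB while leaving
#' passband amplitudes within a few percent.
#'
#' @param record An [eeg_record()].
#' @param low,high Band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @param order Poles per band edge of the Butterworth design.
#' @return An `eeg_record` of identical shape and rate.
#' @examples
#' rec <- eeg_record(matrix(sin(2 * pi * 10 * (0:999) / 500), 1), 500)
#' filt <- bandpass_filter(rec, 2, 25)
#' @export
bandpass_filter <- function(record, low, high, order = 4) {
  if (!inherits(record, "eeg_record")) abort("`record` must be an eeg_record")
  nyq <- record$sample_rate / 2
  if (!(low > 0 && high > low && high < nyq)) {
    abort(sprintf(
      "band (%g, %g) Hz violates 0 < low < high < Nyquist (%g Hz)",
      low, high, nyq
    ))
  }
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- record
  out$samples <- t(apply(record$samples, 1, function(x) {
    as.numeric(signal::filter(flt, x))
  }))
  rownames(out$samples) <- record$channel_names
  out
}

# Filter a bare numeric vector (used per-window by the EMG validator).
bandpass_vector <- function(x, low, high, sample_rate, order = 4) {
  nyq <- sample_rate / 2
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  as.numeric(signal::filter(flt, x))
}

# Steady-state amplitude gain of the band-limiting filter for white noise:
# sqrt of the impulse-response energy. Used to calibrate generator amplitudes.
noise_gain <- function(low, high, sample_rate, order = 4, n = 8192) {
  h <- bandpass_vector(c(1, rep(0, n - 1)), low, high, sample_rate, order)
  sqrt(sum(h^2))
}
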