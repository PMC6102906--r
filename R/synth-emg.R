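#' Jaw-clench EMG model
#'
#' The validation-command channel is emulated as Gaussian noise band-limited
#' to the 55-77 Hz detection band, with a resting in-band standard deviation
#' and a much larger one during voluntary jaw clenches. Defaults are
#' calibrated so the detector-measured 200 ms windowed in-band variances sit
#' below 100 at rest and above 1500 during a clench with wide margin: a
#' 0.2 s window of a 22 Hz-wide band has only ~13 effective degrees of
#' freedom, and the detector re-filters each window from zero state, which
#' can suppress all but a few percent of an unlucky window's energy - so the
#' clench level sits far above threshold (measured clench power "exceeds
#' thousands", as in real jaw-clench EMG).
#'
#' @param rest_inband_std Resting in-band standard deviation, microvolts.
#' @param clench_inband_std In-band standard deviation during a clench.
#' @param band Detection band, Hz.
#' @param sample_rate Hz.
#' @return An object of class `emg_model`.
#' @export
emg_model <- function(rest_inband_std = 4, clench_inband_std = 400,
                      band = c(55, 77), sample_rate = 500) {
  if (rest_inband_std < 0) abort("`rest_inband_std` must be >= 0")
  if (clench_inband_std < rest_inband_std) {
    abort("`clench_inband_std` must be >= `rest_inband_std`")
  }
  structure(
    list(
      rest_inband_std = rest_inband_std,
      clench_inband_std = clench_inband_std,
      band = band, sample_rate = sample_rate
    ),
    class = "emg_model"
  )
}

#' Simulate a single-channel EMG trace with jaw-clench bursts
#'
#' Stationary band-limited Gaussian noise is generated by causal filtering of
#' white noise into `model$band` (scaled by the filter's noise gain so the
#' in-band standard deviation is met exactly in expectation), then amplitude-
#' modulated: `rest_inband_std` outside clench intervals, `clench_inband_std`
#' inside. Envelope edges are sharp, so in-band power rises and falls with
#' the clench on the sample grid.
#'
#' @param duration Trace length, seconds.
#' @param clench_intervals List of `c(start, end)` pairs in seconds,
#'   non-overlapping, within `[0, duration]`.
#' @param model An [emg_model()].
#' @param channel_name Name of the single channel (FCz by default).
#' @param seed Optional integer seed.
#' @return A single-channel [eeg_record()].
#' @examples
#' trace <- synth_emg_trace(3, list(c(1, 2)), seed = 1)
#' @export
synth_emg_trace <- function(duration, clench_intervals = list(),
                            model = emg_model(), channel_name = "FCz",
                            seed = NULL) {
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (length(clench_intervals) > 0) {
    iv <- do.call(rbind, lapply(clench_intervals, function(x) {
      if (length(x) != 2 || x[2] <= x[1]) {
        abort("each clench interval must be c(start, end) with end > start")
      }
      x
    }))
    if (any(iv < 0) || any(iv > duration)) {
      abort("clench intervals must lie within [0, duration]")
    }
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2])) {
      abort("clench intervals must not overlap")
    }
  }
  fs <- model$sample_rate
  n <- round(duration * fs)
  times <- (seq_len(n) - 1) / fs

  x <- with_seed(seed, {
    if (model$clench_inband_std == 0 && model$rest_inband_std == 0) {
      numeric(n)
    } else {
      # warm-up samples discarded so the band-limited noise is stationary
      warm <- 1000L
      white <- stats::rnorm(n + warm)
      g <- noise_gain(model$band[1], model$band[2], fs)
      band <- bandpass_vector(
        white, model$band[1], model$band[2], fs
      )[(warm + 1):(warm + n)] / g
      env <- rep(model$rest_inband_std, n)
      for (k in seq_along(clench_intervals)) {
        a <- clench_intervals[[k]][1]
        b <- clench_intervals[[k]][2]
        env[times >= a & times < b] <- model$clench_inband_std
      }
      band * env
    }
  })
  eeg_record(matrix(x, 1),
    sample_rate = fs, channel_names = channel_name, start_time = 0
  )
}
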