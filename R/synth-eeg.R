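#' Default EEG montage
#'
#' The twelve signal electrodes used by the stack, frontal to parietal.
#' @return Character vector of channel names.
#' @export
default_montage <- function() {
  c(
    "F3", "F4", "FC1", "FC2", "C3", "Cz", "C4",
    "CP1", "CP2", "P3", "Pz", "P4"
  )
}

# Centro-parietal spatial profile of the P300: maximal at Pz, decaying
# toward frontal sites. Values are relative gains.
default_channel_gains <- function(channel_names = default_montage()) {
  base <- c(
    F3 = 0.30, F4 = 0.30, FC1 = 0.40, FC2 = 0.40, C3 = 0.50, Cz = 0.70,
    C4 = 0.50, CP1 = 0.80, CP2 = 0.80, P3 = 0.90, Pz = 1.00, P4 = 0.90
  )
  g <- base[channel_names]
  g[is.na(g)] <- 0.5
  names(g) <- channel_names
  g
}

#' Event-related-potential model for the synthetic EEG generator
#'
#' The P300 is emulated as a Gaussian bump riding on noise: peak
#' `p300_amplitude` microvolts at `p300_latency` seconds after an attended
#' stimulus onset, temporal spread `p300_width` (Gaussian sigma), spatial
#' profile `channel_gains` (maximal over centro-parietal sites).
#'
#' @param p300_amplitude Peak amplitude on the max-gain channel, microvolts.
#' @param p300_latency Peak latency after stimulus onset, seconds.
#' @param p300_width Gaussian sigma of the bump, seconds.
#' @param channel_gains Named per-channel scaling (length = channel count).
#' @param noise_std Additive noise standard deviation, microvolts.
#' @param noise_spectrum `"white"` or `"one_over_f"`.
#' @return An object of class `erp_model`.
#' @export
erp_model <- function(p300_amplitude = 5, p300_latency = 0.3,
                      p300_width = 0.06,
                      channel_gains = default_channel_gains(),
                      noise_std = 10,
                      noise_spectrum = c("white", "one_over_f")) {
  noise_spectrum <- match.arg(noise_spectrum)
  if (p300_amplitude < 0 || p300_width < 0 || noise_std < 0) {
    abort("amplitude, width and noise_std must be >= 0")
  }
  structure(
    list(
      p300_amplitude = p300_amplitude, p300_latency = p300_latency,
      p300_width = p300_width, channel_gains = channel_gains,
      noise_std = noise_std, noise_spectrum = noise_spectrum
    ),
    class = "erp_model"
  )
}

# 1/f-shaped Gaussian noise, unit variance, by spectral shaping.
one_over_f_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))
  freq <- pmin(freq, n - freq + 1) # symmetric shaping
  shaped <- spec / sqrt(freq)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Simulate an EEG session for a stimulus schedule
#'
#' Generates a multichannel record covering the schedule plus an 800 ms tail.
#' Every intensification of `attended_index` adds the ERP bump (scaled by the
#' per-channel gains); all other epochs carry noise only.
#'
#' @param schedule A [make_stimulus_schedule()] result (one or more trials).
#' @param attended_index Stimulus index the simulated user attends; must be
#'   in the schedule's active set.
#' @param erp An [erp_model()].
#' @param sample_rate Hz.
#' @param seed Optional integer seed.
#' @return An [eeg_record()] with one channel per entry of
#'   `erp$channel_gains`.
#' @export
synth_eeg_session <- function(schedule, attended_index, erp = erp_model(),
                              sample_rate = 500, seed = NULL) {
  active <- attr(schedule, "active_set") %||% unique(schedule$stimulus_index)
  if (!attended_index %in% active) {
    abort(sprintf(
      "attended_index %d is not in the schedule's active set", attended_index
    ))
  }
  ch <- names(erp$channel_gains)
  n_ch <- length(erp$channel_gains)
  t0 <- min(schedule$onset_s)
  soa <- attr(schedule, "t_intensify") + attr(schedule, "t_interval")
  t_end <- max(schedule$onset_s) + soa + 0.8
  n <- round((t_end - t0) * sample_rate)
  times <- t0 + (seq_len(n) - 1) / sample_rate

  samples <- with_seed(seed, {
    noise <- if (erp$noise_std == 0) {
      matrix(0, n_ch, n)
    } else if (erp$noise_spectrum == "white") {
      matrix(stats::rnorm(n_ch * n, sd = erp$noise_std), n_ch, n)
    } else {
      t(vapply(seq_len(n_ch), function(i) one_over_f_noise(n) * erp$noise_std,
        numeric(n)
      ))
    }
    noise
  })

  if (erp$p300_amplitude > 0) {
    onsets <- schedule$onset_s[schedule$stimulus_index == attended_index]
    gains <- as.numeric(erp$channel_gains)
    for (on in onsets) {
      lo <- max(1L, floor((on - t0) * sample_rate) + 1L)
      hi <- min(n, ceiling((on + 0.8 - t0) * sample_rate) + 1L)
      idx <- lo:hi
      bump <- erp$p300_amplitude *
        exp(-((times[idx] - on - erp$p300_latency)^2) /
          (2 * erp$p300_width^2))
      samples[, idx] <- samples[, idx] + outer(gains, bump)
    }
  }
  eeg_record(samples,
    sample_rate = sample_rate, channel_names = ch, start_time = t0
  )
}
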