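#' Multichannel signal record
#'
#' Container for sampled biosignals (EEG or EMG): a channels x time matrix in
#' microvolts with a sample rate and start time. Used both by the synthetic
#' generators and the decoding/validation pipelines.
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_names Character vector, one per row of `samples`.
#' @param start_time Time of the first sample, seconds.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sample_rate = 500,
                       channel_names = NULL, start_time = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix (channels x time)")
  }
  stopifnot_scalar_number(sample_rate, "sample_rate", positive = TRUE)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    abort("`channel_names` length must equal the number of channels")
  }
  rownames(samples) <- channel_names
  structure(
    list(
      samples = samples, sample_rate = sample_rate,
      channel_names = channel_names, start_time = start_time
    ),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channel(s) x %d samples @ %g Hz (%.3f s from t=%.3f)\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate,
    ncol(x$samples) / x$sample_rate, x$start_time
  ))
  invisible(x)
}

# Sample times of a record, seconds (first sample at start_time).
record_times <- function(record) {
  record$start_time + (seq_len(ncol(record$samples)) - 1) / record$sample_rate
}

# Duration in seconds.
record_duration <- function(record) ncol(record$samples) / record$sample_rate

#' @export
as_tibble.eeg_record <- function(x, ...) {
  wide <- as_tibble(t(x$samples))
  wide$time_s <- record_times(x)
  tidyr::pivot_longer(wide, -"time_s",
    names_to = "channel", values_to = "uV"
  )
}

#' Plot signal traces
#'
#' Faceted time-series view of each channel, in microvolts.
#'
#' @param object An `eeg_record`.
#' @param channels Optional subset of channel names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_record <- function(object, channels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(channels)) df <- dplyr::filter(df, .data$channel %in% channels)
  ggplot(df, aes(.data$time_s, .data$uV)) +
    geom_line(linewidth = 0.3) +
    facet_grid(rows = vars(.data$channel), scales = "free_y") +
    labs(x = "time (s)", y = expression(mu * V))
}

#' Write / read a signal container
#'
#' Columnar text format: a `time_s` column followed by one column per channel
#' (header row carries channel names). Comma-separated.
#'
#' @param record An `eeg_record`.
#' @param path File path.
#' @return `write_signal()` returns `path` invisibly; `read_signal()` an
#'   `eeg_record` (sample rate recovered from the time column).
#' @export
write_signal <- function(record, path) {
  df <- data.frame(time_s = record_times(record), t(record$samples),
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) abort("signal container lacks a time_s column")
  times <- df$time_s
  if (length(times) < 2) abort("signal container must hold >= 2 samples")
  rate <- 1 / stats::median(diff(times))
  mat <- t(as.matrix(df[setdiff(names(df), "time_s")]))
  eeg_record(mat,
    sample_rate = rate, channel_names = rownames(mat),
    start_time = times[1]
  )
}
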