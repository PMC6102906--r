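#' EMG validation-command detector configuration
#'
#' The validation command is a voluntary jaw clench detected on a single EMG
#' channel: the ongoing signal is cut into contiguous 200 ms windows, each
#' window is band-pass filtered to 55-77 Hz, and its variance is compared to
#' a threshold (1500) to yield a binary clench decision. Decisions enter a
#' length-4 FIFO (oldest to newest) and the command fires when the FIFO
#' matches the cessation pattern `[1,1,0,0]`, i.e. 0.4 s after the clench
#' ends on the window grid.
#'
#' @param window Window length, seconds.
#' @param band Detection band, Hz.
#' @param threshold Variance threshold separating clench from rest.
#' @param pattern Binary length-4 firing pattern, oldest to newest.
#' @param channel_name EMG channel used (FCz in the default montage).
#' @return An object of class `validator_config`.
#' @export
validator_config <- function(window = 0.2, band = c(55, 77),
                             threshold = 1500, pattern = c(1, 1, 0, 0),
                             channel_name = "FCz") {
  stopifnot_scalar_number(window, "window", positive = TRUE)
  stopifnot_scalar_number(threshold, "threshold", positive = TRUE)
  if (length(pattern) != 4 || !all(pattern %in% c(0, 1))) {
    abort("`pattern` must be a binary 4-tuple")
  }
  structure(
    list(
      window = window, band = band, threshold = threshold,
      pattern = as.integer(pattern), channel_name = channel_name
    ),
    class = "validator_config"
  )
}

#' Fresh validator state
#'
#' The FIFO starts empty (all rest decisions) with no previous fire.
#' @return An object of class `validator_state`.
#' @export
new_validator_state <- function() {
  structure(
    list(fifo = c(0L, 0L, 0L, 0L), last_fire_time = NA_real_),
    class = "validator_state"
  )
}

#' Advance the validator by one window
#'
#' Computes the in-band variance of one window, shifts the binary decision
#' into the FIFO and reports whether the validation command fired. A fire
#' clears the FIFO so the same clench cannot fire twice.
#'
#' @param state A [new_validator_state()] (or previous step's state).
#' @param window_samples Numeric vector of raw samples, exactly
#'   `round(window * sample_rate)` long.
#' @param t_end End time of the window, seconds (becomes the fire time).
#' @param cfg A [validator_config()].
#' @param sample_rate Hz.
#' @param filtered Set `TRUE` if `window_samples` are already band-limited;
#'   otherwise the window is filtered internally.
#' @return A list `(state, fired, variance, decision)`.
#' @export
validator_step <- function(state, window_samples, t_end, cfg,
                           sample_rate = 500, filtered = FALSE) {
  n_expect <- round(cfg$window * sample_rate)
  if (length(window_samples) != n_expect) {
    abort(sprintf(
      "window has %d samples; expected %d", length(window_samples), n_expect
    ))
  }
  x <- if (filtered) {
    window_samples
  } else {
    bandpass_vector(window_samples, cfg$band[1], cfg$band[2], sample_rate)
  }
  v <- stats::var(x)
  decision <- as.integer(v > cfg$threshold)
  fifo <- c(state$fifo[-1], decision)
  fired <- all(fifo == cfg$pattern)
  if (fired) {
    fifo <- c(0L, 0L, 0L, 0L)
    state$last_fire_time <- t_end
  }
  state$fifo <- fifo
  list(state = state, fired = fired, variance = v, decision = decision)
}

#' Detect validation commands in an EMG trace
#'
#' Runs the windowed-variance detector over contiguous, non-overlapping
#' windows aligned to the start of the trace. The fire time is the end time
#' of the window that completes the FIFO pattern, so a clench ending at `t`
#' on the window grid fires at `t + 2 * window` (0.4 s by default).
#'
#' @param trace Single-channel [eeg_record()] of raw EMG.
#' @param cfg A [validator_config()].
#' @return A tibble with one row per fire: `time_s`, plus the per-window
#'   diagnostic table as attribute `"windows"` (`t_end`, `variance`,
#'   `decision`).
#' @examples
#' trace <- synth_emg_trace(3, list(c(1, 2)), seed = 1)
#' detect_validations(trace) # fires at 2.4 s
#' @export
detect_validations <- function(trace, cfg = validator_config()) {
  if (!inherits(trace, "eeg_record")) abort("`trace` must be an eeg_record")
  if (nrow(trace$samples) != 1) abort("`trace` must be single-channel")
  fs <- trace$sample_rate
  wlen <- round(cfg$window * fs)
  if (ncol(trace$samples) < wlen) abort("trace shorter than one window")
  n_win <- floor(ncol(trace$samples) / wlen)
  x <- trace$samples[1, ]
  state <- new_validator_state()
  fires <- numeric(0)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1) * wlen + 1):(w * wlen)]
    t_end <- trace$start_time + w * cfg$window
    res <- validator_step(state, seg, t_end, cfg, sample_rate = fs)
    state <- res$state
    if (res$fired) fires <- c(fires, t_end)
    rows[[w]] <- tibble(
      t_end = t_end, variance = res$variance, decision = res$decision
    )
  }
  out <- tibble(time_s = fires)
  attr(out, "windows") <- bind_rows(rows)
  out
}

#' Write validation fire events as JSON lines
#'
#' @param fires Tibble from [detect_validations()].
#' @param path Output path; one `{"time_s": ...}` object per line.
#' @return `path`, invisibly.
#' @export
write_validations <- function(fires, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (t in fires$time_s) {
    writeLines(jsonlite::toJSON(list(time_s = t), auto_unbox = TRUE), con)
  }
  invisible(path)
}
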