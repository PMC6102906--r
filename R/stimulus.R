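#' Build a randomized oddball stimulus schedule
#'
#' One *sequence* intensifies every stimulus in the active set exactly once,
#' in seeded-random order; a *trial* concatenates `n_sequences` sequences.
#' With the default six stimuli, 120 ms intensification and 80 ms
#' inter-stimulus interval, a three-sequence trial spans
#' 6 x 0.2 s x 3 = 3.6 s.
#'
#' @param active_set Integer vector of stimulus indices (subset of 0:5).
#' @param n_sequences Number of sequences per trial (>= 1).
#' @param t_intensify Intensification duration in seconds.
#' @param t_interval Inter-stimulus interval in seconds.
#' @param trial_id Integer trial identifier stored on each event.
#' @param start_time Onset of the first stimulus, seconds.
#' @param seed Optional integer seed; fixed seed gives an identical schedule.
#'
#' @return A tibble of class `stim_schedule` with one row per intensification
#'   and columns `onset_s`, `stimulus_index`, `sequence_index`, `trial_id`.
#'   Attributes `t_intensify`, `t_interval`, `n_sequences`, `active_set` carry
#'   the timing model; `schedule_span()` returns the total trial duration.
#' @examples
#' sched <- make_stimulus_schedule(0:5, n_sequences = 3, seed = 1)
#' schedule_span(sched) # 3.6 s
#' @export
make_stimulus_schedule <- function(active_set = 0:5, n_sequences = 3,
                                   t_intensify = 0.12, t_interval = 0.08,
                                   trial_id = 1L, start_time = 0,
                                   seed = NULL) {
  active_set <- sort(unique(as.integer(active_set)))
  if (length(active_set) == 0L) abort("`active_set` must be non-empty")
  if (any(active_set < 0L) || any(active_set > 5L)) {
    abort("`active_set` indices must lie in 0..5 (six display stimuli)")
  }
  if (n_sequences < 1L) abort("`n_sequences` must be >= 1")
  stopifnot_scalar_number(t_intensify, "t_intensify", positive = TRUE)
  stopifnot_scalar_number(t_interval, "t_interval", positive = TRUE)

  k <- length(active_set)
  soa <- t_intensify + t_interval
  order <- with_seed(seed, {
    unlist(lapply(seq_len(n_sequences), function(i) sample(active_set, k)))
  })
  events <- tibble(
    onset_s = start_time + soa * (seq_along(order) - 1),
    stimulus_index = as.integer(order),
    sequence_index = rep(seq_len(n_sequences), each = k),
    trial_id = as.integer(trial_id)
  )
  structure(events,
    class = c("stim_schedule", class(events)),
    t_intensify = t_intensify, t_interval = t_interval,
    n_sequences = as.integer(n_sequences), active_set = active_set,
    start_time = start_time
  )
}

#' Total duration of a stimulus schedule
#'
#' @param schedule A `stim_schedule`.
#' @return Span in seconds from the first onset to the end of the last
#'   inter-stimulus interval.
#' @export
schedule_span <- function(schedule) {
  soa <- attr(schedule, "t_intensify") + attr(schedule, "t_interval")
  nrow(schedule) * soa
}

#' Write / read stimulus event tables
#'
#' Events are exchanged as TSV with columns `onset_s`, `stimulus_index`,
#' `sequence_index`, `trial_id` and `attended` (0/1).
#'
#' @param schedule A `stim_schedule`.
#' @param path File path.
#' @param attended_index Stimulus index the user attends (marks `attended`).
#' @return `write_event_table()` returns `path` invisibly; `read_event_table()`
#'   returns a tibble.
#' @export
write_event_table <- function(schedule, path, attended_index = NA_integer_) {
  df <- as.data.frame(schedule)
  df$attended <- as.integer(!is.na(attended_index) &
    df$stimulus_index == attended_index)
  utils::write.table(df, path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
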