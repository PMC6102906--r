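#' Compute the evaluation metrics from a session log
#'
#' Reduces a closed-loop [run_session()] log to the standard metric set:
#' * `TrP3` - mean number of P300 trials needed per correct selection;
#' * `TiP3` - `TrP3` multiplied by the trial duration (3.6 s with six
#'   stimuli, three sequences and 120/80 ms timing), seconds;
#' * `VT` - mean validation time: the delay from the correct prediction
#'   being displayed to the validation command, seconds;
#' * `FV` - count of false validations (validations outside the predefined
#'   necessary ones);
#' * `SR` - success indicator of the session (fraction over sessions when
#'   aggregated);
#' * `EP` - environment-perception deductions (localization/tracking
#'   failures, arm rejections);
#' * `NV` - navigation deductions (planning failure while a path existed,
#'   collisions, deadloops).
#'
#' @param log A `session_log` (or a bare event tibble plus
#'   `trial_duration`).
#' @param trial_duration Seconds per P300 trial (defaults to the log's).
#' @return A one-row tibble with columns `TrP3`, `TiP3`, `VT`, `FV`, `SR`,
#'   `EP`, `NV`, `n_selections`.
#' @export
compute_metrics <- function(log, trial_duration = NULL) {
  if (inherits(log, "session_log")) {
    events <- log$events
    trial_duration <- trial_duration %||% log$trial_duration
    sr <- as.numeric(log$success)
  } else {
    events <- log
    trial_duration <- trial_duration %||% 3.6
    if (!is_tibble(events) || !all(c("t", "type") %in% names(events))) {
      abort("malformed session log: need an event tibble with t and type")
    }
    sr <- as.numeric(!any(events$type == "session_failed"))
  }
  if (!is_tibble(events) || !all(c("t", "type") %in% names(events))) {
    abort("malformed session log: need an event tibble with t and type")
  }
  trials <- events %>%
    filter(.data$type == "p300_trial") %>%
    group_by(.data$step) %>%
    summarise(n_trials = max(.data$trial), .groups = "drop")
  trp3 <- if (nrow(trials)) mean(trials$n_trials) else NA_real_
  vt <- events %>% filter(.data$type == "validation_delay")
  vt <- if (nrow(vt)) mean(vt$delay) else NA_real_
  fv <- if ("necessary" %in% names(events)) {
    sum(events$type == "validation" & !events$necessary, na.rm = TRUE)
  } else {
    0L
  }
  ep <- sum(events$type %in% c(
    "localization_failure", "tracking_failure", "solution_rejected"
  ))
  notes <- if ("note" %in% names(events)) events$note else
    rep(NA_character_, nrow(events))
  nv <- sum(events$type %in% c("collision", "deadloop")) +
    sum(events$type == "nav_failure" & notes == "planning_failure",
      na.rm = TRUE
    )
  tibble(
    TrP3 = trp3, TiP3 = trp3 * trial_duration, VT = vt,
    FV = as.integer(fv), SR = sr, EP = as.integer(ep), NV = as.integer(nv),
    n_selections = nrow(trials)
  )
}

#' Aggregate per-session metrics
#'
#' Means and standard deviations across sessions, in the shape of the
#' per-subject evaluation tables (TrP3, TiP3, VT, FV columns plus SR and
#' deduction totals).
#'
#' @param metrics Tibble of per-session rows from [compute_metrics()].
#' @return A one-row tibble with `<metric>_mean` / `<metric>_sd` columns,
#'   `SR` (fraction of successful sessions), and summed `FV`, `EP`, `NV`.
#' @export
aggregate_metrics <- function(metrics) {
  tibble(
    n_sessions = nrow(metrics),
    TrP3_mean = mean(metrics$TrP3, na.rm = TRUE),
    TrP3_sd = sd(metrics$TrP3, na.rm = TRUE),
    TiP3_mean = mean(metrics$TiP3, na.rm = TRUE),
    TiP3_sd = sd(metrics$TiP3, na.rm = TRUE),
    VT_mean = mean(metrics$VT, na.rm = TRUE),
    VT_sd = sd(metrics$VT, na.rm = TRUE),
    FV = sum(metrics$FV),
    SR = mean(metrics$SR),
    EP = sum(metrics$EP),
    NV = sum(metrics$NV)
  )
}

#' Plot per-session metrics
#'
#' @param metrics Per-session metric tibble ([compute_metrics()] rows).
#' @return A ggplot: TrP3 and VT per session.
#' @export
plot_metrics <- function(metrics) {
  df <- metrics %>%
    mutate(session = row_number()) %>%
    tidyr::pivot_longer(c("TrP3", "VT"),
      names_to = "metric", values_to = "value"
    )
  ggplot(df, aes(.data$session, .data$value)) +
    geom_col(width = 0.7) +
    facet_wrap(vars(.data$metric), scales = "free_y") +
    labs(x = "session", y = NULL)
}
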