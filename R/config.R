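#' Load and validate a run configuration
#'
#' One YAML file with per-module sections (`decoder`, `validator`, `camera`,
#' `erp`, `emg`, `session`); omitted fields fall back to package defaults.
#'
#' @param path Path to a YAML config, or `NULL` for all defaults.
#' @param overrides Named list applied on top of the file (CLI flags).
#' @return A list of class `run_config` with materialized component
#'   configurations.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  dec <- raw$decoder %||% list()
  cfg <- list(
    decoder = list(
      p_enter = dec$p_enter %||% 0.10,
      p_remove = dec$p_remove %||% 0.15,
      max_features = dec$max_features %||% 60,
      decim = dec$decim %||% 25,
      band = dec$band %||% c(2, 25),
      n_sequences = dec$n_sequences %||% 3
    ),
    validator = do.call(validator_config, raw$validator %||% list()),
    camera = do.call(camera_model, raw$camera %||% list()),
    erp = do.call(erp_model, raw$erp %||% list()),
    emg = do.call(emg_model, raw$emg %||% list()),
    session = raw$session %||% list(),
    seed = raw$seed %||% 1L
  )
  structure(cfg, class = "run_config")
}

# Reproducibility manifest: config fingerprint, seed, package version.
write_manifest <- function(cfg, seed, out_dir, extra = list()) {
  manifest <- c(
    list(
      config_hash = rlang::hash(cfg),
      seed = seed,
      package = "neurochair",
      version = as.character(utils::packageVersion("neurochair")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    extra
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

#' Calibrate the P300 decoder on synthetic training data
#'
#' Generates a calibration session (five sets of twelve trials each by
#' default, 60 trials), trains the SWLDA decoder on target/nontarget epochs
#' and writes the model JSON plus a calibration report with cross-validated
#' single-trial accuracy (leave-one-set-out).
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [run_config()].
#' @param n_sets,trials_per_set Calibration structure.
#' @param seed Integer seed (all generation is derived from it).
#' @return Invisibly, a list with `model`, `report` and the output paths.
#' @export
calibrate_decoder <- function(out_dir, config = run_config(),
                              n_sets = 5, trials_per_set = 12,
                              seed = config$seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dec <- config$decoder
  with_seed(seed, {
    sets <- purrr::map(seq_len(n_sets), function(set) {
      purrr::map(seq_len(trials_per_set), function(k) {
        attended <- sample(0:5, 1)
        sched <- make_stimulus_schedule(0:5, dec$n_sequences,
          trial_id = (set - 1) * trials_per_set + k
        )
        rec <- synth_eeg_session(sched, attended, config$erp)
        rec <- bandpass_filter(rec, dec$band[1], dec$band[2])
        feats <- extract_epochs_and_featurize(rec, sched, decim = dec$decim)
        feats$label <- ifelse(
          feats$stimulus_index == attended, "target", "nontarget"
        )
        feats$attended <- attended
        feats$set <- set
        feats
      }) %>% bind_rows()
    })
    all_feats <- bind_rows(sets)
    model <- train_swlda(
      all_feats, all_feats$label,
      p_enter = dec$p_enter, p_remove = dec$p_remove,
      max_features = dec$max_features
    )
    # leave-one-set-out cross-validated trial accuracy
    cv <- purrr::map_dbl(seq_len(n_sets), function(held) {
      train <- bind_rows(sets[-held])
      test <- sets[[held]]
      m <- train_swlda(
        train, train$label,
        p_enter = dec$p_enter, p_remove = dec$p_remove,
        max_features = dec$max_features
      )
      correct <- vapply(unique(test$trial_id), function(tid) {
        df <- test[test$trial_id == tid, ]
        score_and_classify(m, df, 0:5)$selected_index == df$attended[1]
      }, logical(1))
      mean(correct)
    })
    report <- list(
      n_trials = n_sets * trials_per_set,
      n_selected_features = length(model$selected),
      cv_trial_accuracy = mean(cv),
      cv_by_set = cv,
      train_r_squared = model$r_squared
    )
    model_path <- file.path(out_dir, "swlda_model.json")
    report_path <- file.path(out_dir, "calibration_report.json")
    write_swlda(model, model_path)
    jsonlite::write_json(report, report_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    write_manifest(config, seed, out_dir, list(step = "calibrate"))
    invisible(list(
      model = model, report = report,
      model_path = model_path, report_path = report_path
    ))
  })
}

#' Run repeated closed-loop evaluation sessions
#'
#' Runs `n_sessions` sessions of a scenario, writes per-session metrics
#' (CSV, one row per session with TrP3, TiP3, VT, FV, SR, EP, NV columns),
#' the aggregate means and standard deviations, the per-session event logs
#' (JSON lines) and a reproducibility manifest.
#'
#' @param scenario A scenario (see [scenario_a()]) or `"A"`/`"B"`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @param n_sessions Number of repeated sessions.
#' @param decoder `"ideal"`, a path to a model JSON, or an `swlda` object.
#' @param user A [simulated_user()]; defaults to one using the config's ERP
#'   and EMG models.
#' @param seed Integer master seed; session `i` uses `seed + i`.
#' @return Invisibly, a list with `metrics` (per-session tibble),
#'   `aggregate` and the output paths.
#' @export
run_evaluation <- function(scenario = "A", out_dir = tempfile("neurochair_"),
                           config = run_config(), n_sessions = 10,
                           decoder = "ideal", user = NULL,
                           seed = config$seed) {
  if (is.character(scenario)) {
    scenario <- switch(scenario,
      A = scenario_a(), B = scenario_b(),
      abort("unknown scenario; use 'A', 'B' or a scenario object")
    )
  }
  if (is.character(decoder) && !identical(decoder, "ideal")) {
    if (!file.exists(decoder)) {
      abort(sprintf(
        "decoder model '%s' not found; run calibrate_decoder() first",
        decoder
      ))
    }
    decoder <- read_swlda(decoder)
  }
  if (is.null(user)) {
    user <- if (identical(decoder, "ideal")) {
      ideal_user()
    } else {
      simulated_user(erp = config$erp, emg = config$emg)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logs <- vector("list", n_sessions)
  rows <- vector("list", n_sessions)
  for (i in seq_len(n_sessions)) {
    log <- run_session(scenario,
      user = user, decoder = decoder,
      camera = config$camera, seed = seed + i,
      n_sequences = config$decoder$n_sequences
    )
    logs[[i]] <- log
    rows[[i]] <- compute_metrics(log) %>% mutate(session = i)
    log_path <- file.path(out_dir, sprintf("session_%02d.jsonl", i))
    con <- file(log_path, "w")
    for (j in seq_len(nrow(log$events))) {
      row <- as.list(log$events[j, ])
      row <- row[!vapply(row, function(v) is.na(v)[1], logical(1))]
      writeLines(jsonlite::toJSON(
        row, auto_unbox = TRUE, digits = NA, null = "null"
      ), con)
    }
    close(con)
  }
  metrics <- bind_rows(rows)
  agg <- aggregate_metrics(metrics)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
    row.names = FALSE
  )
  utils::write.csv(agg, file.path(out_dir, "metrics_aggregate.csv"),
    row.names = FALSE
  )
  write_manifest(config, seed, out_dir, list(
    step = "run_scenario", scenario = scenario$name, n_sessions = n_sessions
  ))
  invisible(list(
    metrics = metrics, aggregate = agg, logs = logs, out_dir = out_dir
  ))
}
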