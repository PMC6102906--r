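#' Extract 800 ms post-stimulus epochs and featurize them
#'
#' For every intensification in the schedule, the 800 ms of signal following
#' the stimulus onset is extracted as an epoch (epochs therefore overlap when
#' onsets are 200 ms apart; no overlap correction is applied). Each epoch is
#' reduced to a feature vector by block-mean decimation: consecutive groups
#' of `decim` samples are averaged per channel and the per-channel series are
#' concatenated (channel-major order).
#'
#' @param record An [eeg_record()] (typically already band-pass filtered).
#' @param schedule A [make_stimulus_schedule()] result whose events the
#'   record covers (each onset + 0.8 s must lie inside the record).
#' @param decim Block length in samples; `decim = 1` keeps raw samples.
#' @param epoch_length Epoch duration in seconds.
#' @return A tibble with one row per event: `trial_id`, `stimulus_index`,
#'   `sequence_index`, `onset_s` and a list-column `feature` holding the
#'   numeric feature vector (fixed dimension across the session).
#' @export
extract_epochs_and_featurize <- function(record, schedule, decim = 25,
                                         epoch_length = 0.8) {
  if (!inherits(record, "eeg_record")) abort("`record` must be an eeg_record")
  fs <- record$sample_rate
  n_ep <- round(epoch_length * fs)
  if (decim < 1 || n_ep %% 1 != 0) abort("invalid decimation setup")
  n_blocks <- floor(n_ep / decim)
  if (n_blocks < 1) abort("`decim` exceeds the epoch length")
  n_total <- ncol(record$samples)

  feats <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    onset <- schedule$onset_s[i]
    i0 <- round((onset - record$start_time) * fs) + 1L
    i1 <- i0 + n_ep - 1L
    if (i0 < 1L || i1 > n_total) {
      abort(sprintf(
        "record does not cover event %d (stimulus %d, onset %.3f s)",
        i, schedule$stimulus_index[i], onset
      ))
    }
    ep <- record$samples[, i0:i1, drop = FALSE]
    used <- n_blocks * decim
    # block-mean per channel, then concatenate channels
    dec <- vapply(seq_len(nrow(ep)), function(ch) {
      colMeans(matrix(ep[ch, seq_len(used)], nrow = decim))
    }, numeric(n_blocks))
    feats[[i]] <- as.numeric(dec) # column-major: channel-major concatenation
  }
  tibble(
    trial_id = schedule$trial_id,
    stimulus_index = schedule$stimulus_index,
    sequence_index = schedule$sequence_index,
    onset_s = schedule$onset_s,
    feature = feats
  )
}

# Stack a featurized tibble's list-column into an (events x features) matrix.
feature_matrix <- function(features) {
  do.call(rbind, features$feature)
}
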