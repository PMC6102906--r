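# Synthetic EEG -----------------------------------------------------------

test_that("noise-free ERP peaks at the set amplitude on the max-gain channel", {
  sched <- make_stimulus_schedule(0:5, 1, seed = 2)
  att <- sched$stimulus_index[1]
  rec <- synth_eeg_session(
    sched, att, erp_model(p300_amplitude = 5, noise_std = 0),
    seed = 1
  )
  i <- round((sched$onset_s[1] + 0.3 - rec$start_time) * rec$sample_rate) + 1
  expect_equal(unname(rec$samples["Pz", i]), 5)
  # channel gains scale the bump
  expect_equal(unname(rec$samples["F3", i]), 5 * 0.30)
})

test_that("with zero amplitude, attended and non-attended epochs match", {
  erp <- erp_model(p300_amplitude = 0, noise_std = 10)
  diffs <- vapply(1:20, function(k) {
    sched <- make_stimulus_schedule(0:5, 3, seed = 100 + k)
    rec <- synth_eeg_session(sched, 2, erp, seed = 200 + k)
    feats <- extract_epochs_and_featurize(rec, sched)
    m <- feature_mean <- function(rows) {
      mean(unlist(feats$feature[rows]))
    }
    feature_mean(feats$stimulus_index == 2) -
      feature_mean(feats$stimulus_index != 2)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.5) # no systematic attended effect
})

test_that("ERP energy appears only in attended epochs", {
  erp <- erp_model(p300_amplitude = 5, noise_std = 2)
  sched <- make_stimulus_schedule(0:5, 3, seed = 11)
  rec <- synth_eeg_session(sched, 3, erp, seed = 12)
  feats <- extract_epochs_and_featurize(rec, sched, decim = 1)
  # template on Pz (channel 11 of 12): Gaussian bump at 300 ms
  t_ep <- (seq_len(400) - 1) / 500
  template <- exp(-((t_ep - 0.3)^2) / (2 * 0.06^2))
  pz <- function(v) v[(10 * 400 + 1):(11 * 400)]
  cors <- vapply(seq_len(nrow(feats)), function(i) {
    stats::cor(pz(feats$feature[[i]]), template)
  }, numeric(1))
  att <- feats$stimulus_index == 3
  # per-epoch correlation is noise-limited (~sqrt(SNR/(1+SNR)));
  # non-attended epochs see only overlap leakage from neighbours
  expect_gt(mean(cors[att]), 0.45)
  expect_gt(mean(cors[att]), mean(abs(cors[!att])) + 0.2)
})

test_that("EEG generation is bit-reproducible under a fixed seed", {
  sched <- make_stimulus_schedule(0:5, 2, seed = 5)
  a <- synth_eeg_session(sched, 1, erp_model(), seed = 77)
  b <- synth_eeg_session(sched, 1, erp_model(), seed = 77)
  expect_identical(a$samples, b$samples)
})

test_that("attending an index outside the active set errors", {
  sched <- make_stimulus_schedule(0:2, 2, seed = 1)
  expect_error(synth_eeg_session(sched, 5, erp_model()), "active set")
})

# Synthetic EMG -----------------------------------------------------------

test_that("resting windows stay below 100 and clench windows above 1500", {
  trace <- synth_emg_trace(24, list(c(10, 14)), seed = 31)
  fires <- detect_validations(trace)
  w <- attr(fires, "windows")
  rest <- w$variance[w$t_end <= 10 | w$t_end > 14.4]
  clench <- w$variance[w$t_end > 10.2 & w$t_end <= 14]
  expect_gt(length(rest), 60)
  expect_gt(length(clench), 15)
  expect_lt(max(rest), 100)
  expect_gt(min(clench), 1500)
})

test_that("a zero-amplitude model yields an all-zero trace", {
  trace <- synth_emg_trace(1,
    model = emg_model(rest_inband_std = 0, clench_inband_std = 0),
    seed = 1
  )
  expect_true(all(trace$samples == 0))
})

test_that("overlapping or out-of-range clench intervals are rejected", {
  expect_error(
    synth_emg_trace(5, list(c(1, 2.5), c(2, 3)), seed = 1), "overlap"
  )
  expect_error(
    synth_emg_trace(5, list(c(4, 6)), seed = 1), "within"
  )
})

test_that("an in-band sinusoid of amplitude A has window variance A^2 / 2", {
  fs <- 500
  a <- 60
  t <- (0:(fs * 2 - 1)) / fs
  x <- a * sin(2 * pi * 66 * t) # inside the 55-77 Hz band
  v <- var(neurochair:::bandpass_vector(x[501:600], 55, 77, fs))
  # filter start-up transient inside the window costs some energy
  expect_equal(v, a^2 / 2, tolerance = 0.25)
  # and a full steady-state window matches closely
  y <- neurochair:::bandpass_vector(x, 55, 77, fs)
  expect_equal(var(y[801:900]), a^2 / 2, tolerance = 0.05)
})

test_that("EMG generation is bit-reproducible under a fixed seed", {
  a <- synth_emg_trace(3, list(c(1, 2)), seed = 8)
  b <- synth_emg_trace(3, list(c(1, 2)), seed = 8)
  expect_identical(a$samples, b$samples)
})

test_that("signal containers round-trip through CSV", {
  trace <- synth_emg_trace(1, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal(trace, path)
  back <- read_signal(path)
  expect_equal(back$sample_rate, trace$sample_rate, tolerance = 1e-6)
  expect_equal(back$samples[1, ], trace$samples[1, ],
    tolerance = 1e-6,
    ignore_attr = TRUE
  )
})
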