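test_that("a perfectly separating feature is selected alone", {
  withr::local_seed(2)
  X <- cbind(
    c(rep(1, 10), rep(-1, 10)) + rnorm(20, sd = 0.1),
    rnorm(20)
  )
  fit <- train_swlda(X, rep(c("target", "nontarget"), each = 10))
  expect_identical(fit$selected, 1L)
  expect_length(fit$weights, 1L)
})

test_that("stepwise selection and weights match the brute-force oracle", {
  withr::local_seed(42)
  for (rep in 1:12) {
    n <- sample(10:30, 1)
    p <- sample(3:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p) * rbinom(p, 1, 0.4)
    y <- sign(X %*% beta + rnorm(n, sd = 0.5))
    y[y == 0] <- 1
    if (length(unique(y)) < 2 || min(table(y)) < 2) next
    fit <- train_swlda(X, as.numeric(y),
      p_enter = 0.10, p_remove = 0.15
    )
    orc <- oracle_swlda(X, as.numeric(y),
      p_enter = 0.10, p_remove = 0.15
    )
    expect_identical(fit$selected, as.integer(orc$selected))
    expect_equal(fit$weights, orc$weights, tolerance = 1e-8)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-8)
  }
})

test_that("shuffled labels admit almost no features at p_enter = 0.05", {
  withr::local_seed(9)
  n_selected <- vapply(1:200, function(i) {
    X <- matrix(rnorm(24 * 6), 24, 6)
    y <- rep(c(1, -1), each = 12)[sample(24)]
    fit <- train_swlda(X, y, p_enter = 0.05, p_remove = 0.10)
    length(fit$selected)
  }, numeric(1))
  # false-entry rate near p_enter x p candidates: expect ~0-1 on average
  expect_lt(mean(n_selected), 1)
})

test_that("exactly collinear candidates are skipped, not selected twice", {
  withr::local_seed(5)
  x1 <- c(rep(1, 8), rep(-1, 8)) + rnorm(16, sd = 0.2)
  X <- cbind(x1, x1, rnorm(16)) # column 2 duplicates column 1
  fit <- train_swlda(X, rep(c(1, -1), each = 8))
  expect_false(all(c(1L, 2L) %in% fit$selected))
})

test_that("degenerate inputs are rejected with clear errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_swlda(X, rep(1, 10)), "both classes")
  expect_error(
    train_swlda(X, rep(c(1, -1), 5), p_enter = 0.2, p_remove = 0.1),
    "p_enter"
  )
})

test_that("max_features caps the selected set", {
  withr::local_seed(3)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- sign(rowSums(X) + rnorm(40, sd = 0.1))
  fit <- train_swlda(X, y, p_enter = 0.5, p_remove = 0.6, max_features = 3)
  expect_lte(length(fit$selected), 3L)
})

test_that("tidy and glance summarise the fit", {
  withr::local_seed(2)
  X <- cbind(c(rep(1, 10), rep(-1, 10)) + rnorm(20, 0.1), rnorm(20))
  fit <- train_swlda(X, rep(c(1, -1), each = 10))
  td <- tidy(fit)
  expect_named(td, c("feature", "weight", "entry_order"))
  gl <- glance(fit)
  expect_equal(gl$n_selected, length(fit$selected))
  expect_equal(gl$n_obs, 20L)
})

test_that("models survive a JSON round-trip", {
  withr::local_seed(2)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- sign(X[, 2] + rnorm(30, sd = 0.3))
  fit <- train_swlda(X, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_swlda(fit, path)
  back <- read_swlda(path)
  expect_identical(back$selected, fit$selected)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$intercept, fit$intercept)
})

# Scoring and candidate-restricted classification -------------------------

fake_features <- function(values_by_stim, trial_id = 1L) {
  tibble::tibble(
    trial_id = trial_id,
    stimulus_index = as.integer(names(values_by_stim)),
    sequence_index = 1L,
    onset_s = seq_along(values_by_stim) * 0.2,
    feature = lapply(values_by_stim, function(v) c(v, 0))
  )
}

test_that("all-equal scores break ties toward the lowest candidate index", {
  model <- structure(
    list(selected = integer(0), weights = numeric(0), intercept = 1),
    class = "swlda"
  )
  feats <- fake_features(stats::setNames(as.list(1:6), 0:5))
  out <- score_and_classify(model, feats, 0:5)
  expect_equal(out$selected_index, 0L)
  expect_true(all(out$scores$score == 1))
})

test_that("a singleton candidate set is returned regardless of scores", {
  model <- structure(
    list(selected = 1L, weights = 5, intercept = 0),
    class = "swlda"
  )
  feats <- fake_features(stats::setNames(as.list(c(9, 1, 0, 0, 0, 0)), 0:5))
  out <- score_and_classify(model, feats, candidate_set = 2)
  expect_equal(out$selected_index, 2L)
})

test_that("per-stimulus scores sum across sequences, order-invariantly", {
  model <- structure(
    list(selected = 1L, weights = 1, intercept = 0),
    class = "swlda"
  )
  feats <- dplyr::bind_rows(
    fake_features(stats::setNames(as.list(c(1, 2)), 0:1)),
    fake_features(stats::setNames(as.list(c(3, 5)), 0:1))
  )
  feats$sequence_index <- c(1L, 1L, 2L, 2L)
  out <- score_and_classify(model, feats, 0:1)
  expect_equal(sort(out$scores$score), c(4, 7))
  shuffled <- feats[c(3, 1, 4, 2), ]
  out2 <- score_and_classify(model, shuffled, 0:1)
  expect_equal(out2$scores, out$scores)
})

test_that("the candidate set must be present and non-empty", {
  model <- structure(
    list(selected = integer(0), weights = numeric(0), intercept = 0),
    class = "swlda"
  )
  feats <- fake_features(stats::setNames(as.list(1:3), 0:2))
  expect_error(score_and_classify(model, feats, integer(0)), "non-empty")
  expect_error(score_and_classify(model, feats, c(0, 5)), "subset")
})

test_that("a trained decoder beats chance on held-out synthetic trials", {
  erp <- erp_model(p300_amplitude = 5, noise_std = 10)
  model <- trained_decoder(erp)
  correct <- withr::with_seed(501, {
    vapply(1:25, function(i) {
      att <- sample(0:5, 1)
      feats <- make_decoder_trial(att, erp, seed = 9000L + 11L * i)
      score_and_classify(model, feats, 0:5)$selected_index == att
    }, logical(1))
  })
  expect_gt(mean(correct), 1 / 6)
})
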