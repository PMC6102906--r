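# Independent oracles used to cross-check the implementation.

# Brute-force stepwise regression: at every step refit every candidate
# model with lm() and take partial-F / coefficient p-values from anova()
# and summary(); mirrors the published stepwise conventions (smallest
# p-value enters if < p_enter, largest removed if > p_remove).
oracle_swlda <- function(X, y, p_enter = 0.10, p_remove = 0.15,
                         max_features = ncol(X)) {
  included <- integer(0)
  n <- nrow(X)
  repeat {
    moved <- FALSE
    if (length(included) < max_features && length(included) < ncol(X)) {
      cand <- setdiff(seq_len(ncol(X)), included)
      base_df <- if (length(included)) {
        data.frame(y = y, X[, included, drop = FALSE])
      } else {
        data.frame(y = y)
      }
      fit0 <- stats::lm(y ~ ., data = base_df)
      rss0 <- sum(stats::residuals(fit0)^2)
      pvals <- vapply(cand, function(j) {
        df1 <- cbind(base_df, cand = X[, j])
        fit1 <- stats::lm(y ~ ., data = df1)
        if (anyNA(stats::coef(fit1)["cand"])) {
          return(NA_real_) # exactly collinear candidate
        }
        rss1 <- sum(stats::residuals(fit1)^2)
        if (rss1 <= 1e-10 * rss0) {
          return(0)
        }
        a <- stats::anova(fit0, fit1)
        a[2, "Pr(>F)"]
      }, numeric(1))
      if (any(is.finite(pvals))) {
        best <- which.min(pvals)
        if (is.finite(pvals[best]) && pvals[best] < p_enter) {
          included <- c(included, cand[best])
          moved <- TRUE
        }
      }
    }
    repeat {
      if (length(included) == 0) break
      df <- data.frame(y = y, X[, included, drop = FALSE])
      fit <- stats::lm(y ~ ., data = df)
      sm <- summary(fit)$coefficients
      resid_df <- fit$df.residual
      rss <- sum(stats::residuals(fit)^2)
      if (resid_df <= 0 || rss <= 1e-12 * sum((y - mean(y))^2)) break
      pv <- sm[-1, "Pr(>|t|)"]
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        included <- included[-worst]
      } else {
        break
      }
    }
    if (!moved || length(included) >= max_features) break
  }
  fit <- stats::lm(y ~ ., data = data.frame(y = y, X[, included,
    drop = FALSE
  ]))
  list(
    selected = included,
    weights = unname(stats::coef(fit))[-1],
    intercept = unname(stats::coef(fit))[1]
  )
}

# Brute-force orientation: the axis maximizing projected variance over a
# 1-degree grid of directions.
oracle_principal_axis <- function(xy) {
  angs <- seq(0, 179) * pi / 180
  vs <- vapply(angs, function(a) {
    stats::var(as.numeric(xy %*% c(cos(a), sin(a))))
  }, numeric(1))
  a <- angs[which.max(vs)]
  c(cos(a), sin(a))
}

# Line angle (direction-invariant) between two 2D axes, radians.
axis_angle <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b))))
}

# One synthetic P300 trial: schedule + filtered, featurized epochs with
# labels, ready for training or classification.
make_decoder_trial <- function(attended, erp, trial_id = 1L,
                               n_sequences = 3, seed = NULL) {
  sched <- make_stimulus_schedule(0:5, n_sequences,
    trial_id = trial_id, seed = seed
  )
  rec <- synth_eeg_session(sched, attended, erp,
    seed = if (is.null(seed)) NULL else seed + 1L
  )
  rec <- bandpass_filter(rec, 2, 25)
  feats <- extract_epochs_and_featurize(rec, sched)
  feats$label <- ifelse(
    feats$stimulus_index == attended, "target", "nontarget"
  )
  feats
}

# A trained decoder on n_train seeded trials (shared across tests via
# lazy memoisation in the test environment).
trained_decoder <- local({
  cache <- NULL
  function(erp = erp_model(p300_amplitude = 5, noise_std = 10),
           n_train = 30, seed_base = 7000L) {
    if (!is.null(cache)) {
      return(cache)
    }
    train <- withr::with_seed(seed_base, {
      dplyr::bind_rows(lapply(seq_len(n_train), function(i) {
        make_decoder_trial(sample(0:5, 1), erp,
          trial_id = i, seed = seed_base + 13L * i
        )
      }))
    })
    cache <<- train_swlda(train, train$label)
    cache
  }
})
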