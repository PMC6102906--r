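#' Train a stepwise linear discriminant analysis (SWLDA) decoder
#'
#' Stepwise regression of numeric class labels (+1 target / -1 nontarget) on
#' epoch features. At each forward step the candidate with the smallest
#' partial-F p-value enters if that p-value is below `p_enter`; after every
#' addition, backward elimination removes any included feature whose
#' p-value exceeds `p_remove` (worst first). Stepping ends when no move is
#' possible or `max_features` features are included. The discriminant
#' weights are the ordinary-least-squares coefficients of the labels on the
#' selected features.
#'
#' @param features Featurized epochs: either the tibble returned by
#'   [extract_epochs_and_featurize()] (list-column `feature`) or a numeric
#'   matrix with one row per epoch.
#' @param labels Per-epoch labels: logical (TRUE = target), numeric (+1/-1),
#'   or character/factor with levels `"target"`/`"nontarget"`.
#' @param p_enter Entry threshold on the partial-F p-value.
#' @param p_remove Removal threshold; must be >= `p_enter`.
#' @param max_features Cap on the number of selected features.
#' @return An object of class `swlda` with elements `selected` (feature
#'   indices in entry order), `weights`, `intercept`, the thresholds, and a
#'   `history` tibble of stepwise moves. Supports [tidy()], [glance()] and
#'   [score_and_classify()].
#' @export
train_swlda <- function(features, labels, p_enter = 0.10, p_remove = 0.15,
                        max_features = 60) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  y <- normalize_labels(labels)
  if (nrow(X) != length(y)) abort("features and labels disagree in length")
  if (length(unique(y)) < 2) {
    abort("both classes (target and nontarget) must be present")
  }
  if (min(table(y)) < 2) abort("need >= 2 samples per class")
  if (p_enter > p_remove) {
    abort("`p_enter` must be <= `p_remove` (else stepping can cycle)")
  }
  n <- nrow(X)
  p <- ncol(X)
  included <- integer(0)
  history <- list()
  tol <- 1e-10

  repeat {
    moved <- FALSE
    # ---- forward step ----
    if (length(included) < max_features && length(included) < p) {
      qr_inc <- qr(cbind(1, X[, included, drop = FALSE]))
      ry <- qr.resid(qr_inc, y)
      rss0 <- sum(ry^2)
      cand <- setdiff(seq_len(p), included)
      RX <- qr.resid(qr_inc, X[, cand, drop = FALSE])
      cross <- as.numeric(crossprod(RX, ry))
      ss <- colSums(RX^2)
      scale_ref <- mean(colSums(X[, cand, drop = FALSE]^2)) + tol
      ok <- ss > tol * scale_ref # skip exactly collinear candidates
      df <- n - length(included) - 2L
      if (any(ok) && df > 0 && rss0 > tol) {
        num <- ifelse(ok, cross^2 / ss, NA_real_)
        rss1 <- rss0 - num
        fstat <- num / pmax(rss1 / df, tol * rss0 / df + .Machine$double.xmin)
        pval <- stats::pf(fstat, 1, df, lower.tail = FALSE)
        pval[rss1 <= tol * rss0] <- 0 # perfect fit after addition
        best <- which.min(pval)
        if (length(best) == 1 && is.finite(pval[best]) &&
          pval[best] < p_enter) {
          included <- c(included, cand[best])
          history[[length(history) + 1]] <-
            tibble(action = "add", feature = cand[best], p_value = pval[best])
          moved <- TRUE
        }
      }
    }
    # ---- backward steps ----
    repeat {
      if (length(included) == 0) break
      pv <- coef_p_values(X[, included, drop = FALSE], y)
      worst <- which.max(pv)
      if (length(pv) > 0 && pv[worst] > p_remove) {
        history[[length(history) + 1]] <- tibble(
          action = "remove", feature = included[worst], p_value = pv[worst]
        )
        included <- included[-worst]
      } else {
        break
      }
    }
    if (!moved || length(included) >= max_features) break
  }

  fit <- stats::lm.fit(cbind(1, X[, included, drop = FALSE]), y)
  coefs <- fit$coefficients
  structure(
    list(
      selected = included,
      weights = if (length(included)) unname(coefs[-1]) else numeric(0),
      intercept = unname(coefs[1]),
      p_enter = p_enter, p_remove = p_remove, max_features = max_features,
      n_features = p, n_obs = n,
      r_squared = if (sum((y - mean(y))^2) > 0) {
        1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
      } else {
        NA_real_
      },
      history = if (length(history)) bind_rows(history) else
        tibble(action = character(), feature = integer(), p_value = double())
    ),
    class = "swlda"
  )
}

# Map assorted label encodings to +1 (target) / -1 (nontarget).
normalize_labels <- function(labels) {
  if (is.logical(labels)) {
    return(ifelse(labels, 1, -1))
  }
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (all(u %in% c(-1, 1))) {
      return(as.numeric(labels))
    }
    if (all(u %in% c(0, 1))) {
      return(ifelse(labels > 0, 1, -1))
    }
    abort("numeric labels must be coded +1/-1 or 0/1")
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("target", "nontarget"))) {
    abort("labels must be 'target'/'nontarget' (or logical/numeric)")
  }
  ifelse(lab == "target", 1, -1)
}

# Two-sided p-values of each slope in the OLS fit y ~ 1 + Xsel.
coef_p_values <- function(Xsel, y) {
  Xd <- cbind(1, Xsel)
  fit <- stats::lm.fit(Xd, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  if (df <= 0 || rss <= 1e-12 * sum((y - mean(y))^2)) {
    # saturated or perfect fit: every term maximally significant
    return(rep(0, ncol(Xsel)))
  }
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  XtX_inv <- chol2inv(R)
  se <- sqrt(sigma2 * diag(XtX_inv))[-1]
  tstat <- fit$coefficients[-1] / se
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

#' @export
print.swlda <- function(x, ...) {
  cat(sprintf(
    "<swlda> %d/%d features selected (p_enter %.2g, p_remove %.2g), R^2 %.3f\n",
    length(x$selected), x$n_features, x$p_enter, x$p_remove, x$r_squared
  ))
  invisible(x)
}

#' @describeIn train_swlda One row per selected feature: `feature` index,
#'   `weight`, and the order of entry.
#' @param x,object An `swlda` fit.
#' @param ... Unused.
#' @export
tidy.swlda <- function(x, ...) {
  tibble(
    feature = x$selected,
    weight = x$weights,
    entry_order = seq_along(x$selected)
  )
}

#' @describeIn train_swlda One-row model summary.
#' @export
glance.swlda <- function(x, ...) {
  tibble(
    n_selected = length(x$selected), n_features = x$n_features,
    n_obs = x$n_obs, r_squared = x$r_squared,
    p_enter = x$p_enter, p_remove = x$p_remove,
    max_features = x$max_features
  )
}

#' Plot SWLDA discriminant weights
#'
#' @param object An `swlda` fit.
#' @param ... Unused.
#' @return A ggplot object: weight against feature index for the selected set.
#' @export
autoplot.swlda <- function(object, ...) {
  ggplot(tidy(object), aes(.data$feature, .data$weight)) +
    geom_segment(aes(xend = .data$feature, yend = 0)) +
    geom_point() +
    labs(x = "feature index", y = "discriminant weight")
}

#' Score epochs and classify a trial over a restricted candidate set
#'
#' Each epoch's score is the dot product of the discriminant weights with the
#' selected feature values plus the intercept; per-stimulus scores are summed
#' across sequences within a trial, and the classifier output is the argmax
#' over `candidate_set` only (ties broken toward the lowest stimulus index).
#' Restricting the candidate set to the targets actually on display can only
#' help accuracy, since scores of absent stimuli are ignored.
#'
#' @param model An [train_swlda()] fit.
#' @param features Featurized epochs of one or more trials
#'   ([extract_epochs_and_featurize()] output).
#' @param candidate_set Non-empty set of stimulus indices to classify over;
#'   must be a subset of the indices present in `features`.
#' @return A list with `scores` (tibble: `trial_id`, `stimulus_index`,
#'   `score`, restricted to the candidate set) and `selected` (tibble:
#'   `trial_id`, `selected_index`). For a single trial the chosen index is
#'   also available as `$selected_index`.
#' @export
score_and_classify <- function(model, features, candidate_set = 0:5) {
  candidate_set <- sort(unique(as.integer(candidate_set)))
  if (length(candidate_set) == 0) abort("`candidate_set` must be non-empty")
  present <- unique(features$stimulus_index)
  if (!all(candidate_set %in% present)) {
    abort("`candidate_set` must be a subset of the stimulus indices present")
  }
  X <- feature_matrix(features)
  sel <- model$selected
  ep_score <- if (length(sel)) {
    as.numeric(X[, sel, drop = FALSE] %*% model$weights) + model$intercept
  } else {
    rep(model$intercept, nrow(X))
  }
  scored <- features %>%
    mutate(score = ep_score) %>%
    filter(.data$stimulus_index %in% candidate_set) %>%
    group_by(.data$trial_id, .data$stimulus_index) %>%
    summarise(score = sum(.data$score), .groups = "drop")
  selected <- scored %>%
    group_by(.data$trial_id) %>%
    arrange(desc(.data$score), .data$stimulus_index, .by_group = TRUE) %>%
    slice_head(n = 1) %>%
    ungroup() %>%
    select("trial_id", selected_index = "stimulus_index")
  out <- list(scores = scored, selected = selected)
  if (nrow(selected) == 1) out$selected_index <- selected$selected_index[1]
  out
}

#' Serialize / restore an SWLDA model as JSON
#'
#' @param model An `swlda` fit.
#' @param path File path.
#' @return `write_swlda()` returns `path` invisibly; `read_swlda()` the model.
#' @export
write_swlda <- function(model, path) {
  payload <- list(
    selected = as.integer(model$selected),
    weights = model$weights,
    intercept = model$intercept,
    p_enter = model$p_enter, p_remove = model$p_remove,
    max_features = model$max_features,
    n_features = model$n_features, n_obs = model$n_obs,
    r_squared = model$r_squared
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_swlda
#' @export
read_swlda <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      selected = as.integer(p$selected),
      weights = as.numeric(p$weights),
      intercept = p$intercept,
      p_enter = p$p_enter, p_remove = p$p_remove,
      max_features = p$max_features,
      n_features = p$n_features, n_obs = p$n_obs,
      r_squared = p$r_squared,
      history = NULL
    ),
    class = "swlda"
  )
}
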