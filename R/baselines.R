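#' Cross-validated decoding curve on training data
#'
#' Inner k-fold cross-validation on a training split: per fold a
#' reconvolution CCA decoder is fit on the fold's training part and every
#' validation trial is classified at every decision-window length; accuracies
#' are averaged across folds. This is the ingredient of the static stopping
#' rules.
#'
#' @param trials `K x C x T` array.
#' @param labels Class labels (1-based).
#' @param structures Per-class structure matrices.
#' @param grid Decision-window lengths in samples.
#' @param n_folds Inner folds (default 5).
#' @param similarity `"inner"` or `"pearson"`.
#' @param sample_rate Hz, for the time column.
#' @param seed Seed for the fold assignment.
#' @return A `decoding_curve` tibble: `window`, `window_len`, `time_s`,
#'   `accuracy`.
#' @export
decoding_curve <- function(trials, labels, structures, grid,
                           n_folds = 5, similarity = c("inner", "pearson"),
                           sample_rate = attr(structures[[1]], "sample_rate"),
                           seed = NULL) {
  similarity <- match.arg(similarity)
  K <- dim(trials)[1]
  if (K < n_folds) stop_invalid("fewer trials (%d) than folds (%d)", K, n_folds)
  folds <- stratified_folds(labels, n_folds, seed)
  grid <- as.integer(grid)
  acc <- matrix(NA_real_, n_folds, length(grid))
  for (fo in seq_len(n_folds)) {
    tr <- folds != fo
    te <- !tr
    fit <- fit_rcca(trials[tr, , , drop = FALSE], labels[tr], structures)
    te_idx <- which(te)
    correct <- matrix(FALSE, length(te_idx), length(grid))
    for (j in seq_along(te_idx)) {
      sc <- score_stream(
        trials[te_idx[j], , ], fit$w, fit$templates, grid, similarity
      )
      correct[j, ] <- apply(sc, 1L, classify) == labels[te_idx[j]]
    }
    acc[fo, ] <- colMeans(correct)
  }
  structure(
    tibble::tibble(
      window = seq_along(grid),
      window_len = grid,
      time_s = samples_to_sec(grid, sample_rate),
      accuracy = colMeans(acc)
    ),
    class = c("decoding_curve", class(tibble::tibble()))
  )
}

#' Static stopping rule from a decoding curve
#'
#' Picks a single stopping window for all trials: `"max-accuracy"` takes the
#' earliest window attaining the curve maximum; `"targeted"` the earliest
#' window reaching a predefined targeted accuracy `theta` (falling back to
#' the max-accuracy window when the target is never reached); `"max-itr"` the
#' window maximizing the information transfer rate computed from the curve.
#'
#' @param curve A [decoding_curve()] tibble.
#' @param criterion One of `"max-accuracy"`, `"targeted"`, `"max-itr"`.
#' @param n_classes Number of classes (needed for ITR).
#' @param theta Targeted accuracy for `criterion = "targeted"`.
#' @param overhead_s Inter-trial overhead for the ITR computation.
#' @return A `static_rule` list with `stop_window`, `stop_len`, `stop_time`,
#'   `criterion`.
#' @export
static_rule <- function(curve, criterion = c("max-accuracy", "targeted", "max-itr"),
                        n_classes, theta = NULL, overhead_s = 0) {
  criterion <- match.arg(criterion)
  if (nrow(curve) == 0L) stop_invalid("empty decoding curve")
  jw <- switch(criterion,
    "max-accuracy" = which.max(curve$accuracy),
    "targeted" = {
      if (is.null(theta)) stop_invalid("`theta` required for targeted rule")
      hit <- which(curve$accuracy >= theta)
      if (length(hit) > 0L) hit[1L] else which.max(curve$accuracy)
    },
    "max-itr" = which.max(
      itr(curve$accuracy, n_classes, curve$time_s, overhead_s)
    )
  )
  structure(
    list(
      stop_window = jw, stop_len = curve$window_len[jw],
      stop_time = curve$time_s[jw], criterion = criterion, theta = theta
    ),
    class = "static_rule"
  )
}

#' Calibrate the margin stopping rule
#'
#' For every decision window, computes the margin (best minus runner-up
#' classification score) of each training trial and learns the smallest
#' threshold — among the observed margins — such that the trials at or above
#' it are classified correctly at least a fraction `theta` of the time. A
#' window where no threshold attains the target gets `+Inf` (never stop
#' there).
#'
#' @param streams List of per-trial score-stream matrices
#'   (`n_windows x n_classes`, aligned rows).
#' @param labels True class per trial.
#' @param theta Targeted accuracy in `[0, 1]`.
#' @return A `margin_rule` with per-window `thresholds`.
#' @export
calibrate_margin <- function(streams, labels, theta) {
  assert_scalar_number(theta, "theta", 0, 1)
  n_win <- nrow(streams[[1]])
  n_trials <- length(streams)
  thresholds <- rep(Inf, n_win)
  for (jw in seq_len(n_win)) {
    margins <- numeric(n_trials)
    correct <- logical(n_trials)
    for (k in seq_len(n_trials)) {
      f <- streams[[k]][jw, ]
      ord <- order(f, decreasing = TRUE)
      margins[k] <- f[ord[1L]] - f[ord[2L]]
      correct[k] <- classify(f) == labels[k]
    }
    for (m in sort(unique(margins))) {
      keep <- margins >= m
      if (mean(correct[keep]) >= theta) {
        thresholds[jw] <- m
        break
      }
    }
  }
  structure(
    list(thresholds = thresholds, theta = theta),
    class = "margin_rule"
  )
}

#' Apply the margin stopping rule to one trial's score stream
#'
#' Releases the class with the maximum score at the first window whose margin
#' (best minus runner-up score) reaches that window's learned threshold;
#' forced argmax emission at the final window otherwise.
#'
#' @param scores `n_windows x n_classes` score matrix.
#' @param rule A [calibrate_margin()] rule.
#' @param grid Window lengths in samples (for the stop time).
#' @param sample_rate Hz.
#' @return A `stopping_decision`.
#' @export
apply_margin <- function(scores, rule, grid, sample_rate = NA_real_) {
  scores <- as.matrix(scores)
  n_win <- nrow(scores)
  if (n_win == 0L) stop_invalid("empty score stream")
  for (jw in seq_len(n_win)) {
    f <- scores[jw, ]
    ord <- order(f, decreasing = TRUE)
    margin <- f[ord[1L]] - f[ord[2L]]
    pass <- margin >= rule$thresholds[jw]
    if (pass || jw == n_win) {
      return(new_stopping_decision(
        stop_window = jw,
        stop_time = samples_to_sec(grid[jw], sample_rate),
        predicted = classify(f), forced = !pass,
        score_trace = scores[seq_len(jw), , drop = FALSE]
      ))
    }
  }
}

#' Apply the calibration-free Beta stopping rule to one trial
#'
#' Pearson-correlation scores are mapped to `[0, 1]` via `(rho + 1) / 2`; at
#' each window a Beta distribution is fit by maximum likelihood to all mapped
#' scores except the maximum, and the trial stops when the fitted cumulative
#' probability at the mapped maximum score reaches the targeted accuracy
#' `theta` — i.e. when the best score is an improbably large draw from the
#' distribution of the non-maximum scores. An alternative reading of the
#' outlier criterion, requiring `1 - CDF(max)^(N-1) <= 1 - theta`, is
#' available via `criterion = "family-max"`. Windows with degenerate
#' (all-equal) scores never stop. Forced argmax emission at the final window.
#'
#' @param scores `n_windows x n_classes` matrix of Pearson scores in
#'   `[-1, 1]`.
#' @param theta Targeted accuracy in `[0, 1]`.
#' @param grid Window lengths in samples.
#' @param sample_rate Hz.
#' @param criterion `"cdf"` (default) or `"family-max"`.
#' @return A `stopping_decision`.
#' @export
apply_beta <- function(scores, theta, grid, sample_rate = NA_real_,
                       criterion = c("cdf", "family-max")) {
  criterion <- match.arg(criterion)
  assert_scalar_number(theta, "theta", 0, 1)
  scores <- as.matrix(scores)
  n_win <- nrow(scores)
  if (n_win == 0L) stop_invalid("empty score stream")
  if (ncol(scores) < 3L) stop_invalid("Beta stopping needs at least 3 classes")
  if (any(scores < -1 - 1e-9 | scores > 1 + 1e-9)) {
    stop_invalid("Beta stopping requires bounded (pearson) scores in [-1, 1]")
  }
  for (jw in seq_len(n_win)) {
    f <- (scores[jw, ] + 1) / 2
    imax <- classify(f)
    rest <- f[-imax]
    pass <- FALSE
    if (stats::sd(rest) > 0) {
      fit <- fit_beta_ml(rest)
      p_max <- stats::pbeta(min(max(f[imax], 0), 1), fit$shape1, fit$shape2)
      pass <- if (criterion == "cdf") {
        p_max >= theta
      } else {
        1 - p_max^(ncol(scores) - 1L) <= 1 - theta
      }
    }
    if (pass || jw == n_win) {
      return(new_stopping_decision(
        stop_window = jw,
        stop_time = samples_to_sec(grid[jw], sample_rate),
        predicted = imax, forced = !pass,
        score_trace = scores[seq_len(jw), , drop = FALSE]
      ))
    }
  }
}

# Maximum-likelihood Beta fit with method-of-moments start; values at the
# boundary are clipped inward by 1e-6.
fit_beta_ml <- function(x) {
  x <- pmin(pmax(x, 1e-6), 1 - 1e-6)
  m <- mean(x)
  v <- stats::var(x)
  v <- min(v, m * (1 - m) * 0.99)
  k <- m * (1 - m) / v - 1
  start <- list(shape1 = max(m * k, 1e-3), shape2 = max((1 - m) * k, 1e-3))
  fit <- suppressWarnings(
    fitdistrplus::fitdist(x, "beta", method = "mle", start = start)
  )
  as.list(fit$estimate)
}
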