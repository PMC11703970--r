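#' Decode a set of trials with a stopping rule, logging every decision
#'
#' Scores each trial at every decision window and applies the stopping rule,
#' recording each per-window decision: the argmax class at that window,
#' whether the rule accepted (stopped), the emitted class, and whether the
#' stop was forced at the maximum length. The log is the substrate of the
#' decision-level precision/recall evaluation.
#'
#' @param trials `K x C x T` array.
#' @param labels True class labels (or `NULL` for unlabeled decoding).
#' @param fit An [fit_rcca()] decoder.
#' @param rule A stopping rule: a `bds_model`, `margin_rule`, `static_rule`,
#'   a list `list(type = "fixed", window = j)`, or
#'   `list(type = "beta", theta = ...)`.
#' @param grid Decision-window lengths in samples (defaults to the rule's
#'   grid for `bds_model`).
#' @param similarity Similarity score for non-Beta rules (`"inner"` or
#'   `"pearson"`; the Beta rule always uses Pearson, the Bayesian rule always
#'   the inner product).
#' @return A `decision_log` tibble: one row per visited window per trial with
#'   columns `trial`, `window`, `time_s`, `argmax`, `accepted`, `predicted`,
#'   `forced`, `true_label`.
#' @export
decode_trials <- function(trials, labels, fit, rule, grid = NULL,
                          similarity = c("inner", "pearson")) {
  similarity <- match.arg(similarity)
  if (inherits(rule, "bds_model")) {
    grid <- grid %||% rule$grid
    similarity <- "inner"
  }
  if (is.list(rule) && !is.null(rule$type) && rule$type == "beta") {
    similarity <- "pearson"
  }
  if (is.null(grid)) stop_invalid("`grid` is required for this rule")
  grid <- as.integer(grid)
  K <- dim(trials)[1]
  sample_rate <- fit$sample_rate %||% NA_real_
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    sc <- score_stream(trials[k, , ], fit$w, fit$templates, grid, similarity)
    dec <- apply_rule(sc, rule, grid, sample_rate)
    visited <- seq_len(dec$stop_window)
    rows[[k]] <- tibble::tibble(
      trial = k,
      window = visited,
      time_s = samples_to_sec(grid[visited], sample_rate),
      argmax = apply(sc[visited, , drop = FALSE], 1L, classify),
      accepted = visited == dec$stop_window,
      predicted = ifelse(visited == dec$stop_window, dec$predicted, NA_integer_),
      forced = dec$forced,
      true_label = if (is.null(labels)) NA_integer_ else labels[k]
    )
  }
  structure(
    dplyr::bind_rows(rows),
    class = c("decision_log", class(tibble::tibble()))
  )
}

apply_rule <- function(scores, rule, grid, sample_rate) {
  if (inherits(rule, "bds_model")) {
    return(decide_bds(scores, rule))
  }
  if (inherits(rule, "margin_rule")) {
    return(apply_margin(scores, rule, grid, sample_rate))
  }
  if (inherits(rule, "static_rule")) {
    jw <- rule$stop_window
    return(new_stopping_decision(
      stop_window = jw,
      stop_time = samples_to_sec(grid[jw], sample_rate),
      predicted = classify(scores[jw, ]), forced = FALSE,
      score_trace = scores[seq_len(jw), , drop = FALSE]
    ))
  }
  if (is.list(rule) && !is.null(rule$type)) {
    if (rule$type == "fixed") {
      jw <- rule$window
      return(new_stopping_decision(
        stop_window = jw,
        stop_time = samples_to_sec(grid[jw], sample_rate),
        predicted = classify(scores[jw, ]), forced = FALSE,
        score_trace = scores[seq_len(jw), , drop = FALSE]
      ))
    }
    if (rule$type == "beta") {
      return(apply_beta(scores, rule$theta, grid, sample_rate,
        criterion = rule$criterion %||% "cdf"
      ))
    }
  }
  stop_invalid("unknown stopping rule")
}

#' Count the four decision outcomes over a decision log
#'
#' Each per-window decision is classified against the truth: at windows
#' before the stop (negative decisions), a true class that is winning the
#' argmax counts as a miss (false negative), otherwise a true negative; at
#' the stop window (the one positive decision per trial), a correct emission
#' is a hit (true positive), otherwise a false positive. Forced stops count
#' as positive decisions by default (`forced_positive = FALSE` recounts them
#' as a final negative decision instead).
#'
#' @param log A `decision_log` tibble with truth labels.
#' @param forced_positive Whether a forced stop is a positive decision.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(log, forced_positive = TRUE) {
  if (any(is.na(log$true_label))) {
    stop_invalid("decision log has no truth labels")
  }
  pre <- !log$accepted
  stop_rows <- log$accepted
  if (!forced_positive) {
    demote <- stop_rows & log$forced
    pre <- pre | demote
    stop_rows <- stop_rows & !log$forced
  }
  fn <- sum(log$argmax[pre] == log$true_label[pre])
  tn <- sum(pre) - fn
  tp <- sum(log$predicted[stop_rows] == log$true_label[stop_rows])
  fp <- sum(stop_rows) - tp
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> tp %d, fp %d, tn %d, fn %d\n", x$tp, x$fp, x$tn, x$fn
  ))
  invisible(x)
}

zero_div <- function(num, den) {
  if (den <= 0) {
    inform("zero denominator in a rate; defining the rate as 0")
    return(0)
  }
  num / den
}

#' Relevance-based rates from decision-outcome counts
#'
#' `precision()` is the fraction of true positives among positive decisions,
#' `recall()` the fraction among all detectable instances, `specificity()`
#' the true negative rate, and `f_score()` the harmonic mean of precision and
#' recall. Zero denominators yield 0 with a diagnostic message.
#'
#' @param counts A [confusion_counts()] object.
#' @return A single rate in `[0, 1]`.
#' @export
precision <- function(counts) zero_div(counts$tp, counts$tp + counts$fp)

#' @rdname precision
#' @export
recall <- function(counts) zero_div(counts$tp, counts$tp + counts$fn)

#' @rdname precision
#' @export
specificity <- function(counts) zero_div(counts$tn, counts$tn + counts$fp)

#' @rdname precision
#' @export
f_score <- function(counts) {
  p <- suppressMessages(precision(counts))
  r <- suppressMessages(recall(counts))
  zero_div(2 * p * r, p + r)
}

#' Information transfer rate (Wolpaw definition)
#'
#' Bits per selection
#' `log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))` with the limits at
#' `P = 0` and `P = 1` taken, negative bit rates clipped to zero, converted
#' to bits per minute over the selection time plus overhead.
#'
#' @param accuracy Selection accuracy `P` in `[0, 1]` (vectorized).
#' @param n_classes Number of alternatives `N >= 2`.
#' @param trial_time_s Selection time in seconds (vectorized).
#' @param overhead_s Inter-trial overhead in seconds.
#' @return ITR in bits/min.
#' @export
itr <- function(accuracy, n_classes, trial_time_s, overhead_s = 0) {
  if (n_classes < 2L) stop_invalid("`n_classes` must be >= 2")
  p <- pmin(pmax(accuracy, 0), 1)
  bits <- log2(n_classes) +
    ifelse(p > 0, p * log2(p), 0) +
    ifelse(p < 1, (1 - p) * log2((1 - p) / (n_classes - 1)), 0)
  bits <- pmax(bits, 0)
  bits * 60 / (trial_time_s + overhead_s)
}

#' Specify a stopping method for cross-validated evaluation
#'
#' @param name One of `"bds"`, `"fixed"`, `"static-acc"`, `"static-target"`,
#'   `"static-itr"`, `"margin"`, `"beta"`.
#' @param zeta Cost ratio (Bayesian rule).
#' @param theta Targeted accuracy (static-target, margin, Beta rules).
#' @param similarity `"inner"` or `"pearson"` where the rule supports both.
#' @param fixed_len_s Fixed trial length in seconds (fixed rule; defaults to
#'   the full trial).
#' @param overhead_s Inter-trial overhead used in ITR.
#' @return A `method_spec` list.
#' @export
method_spec <- function(name = c(
                          "bds", "fixed", "static-acc", "static-target",
                          "static-itr", "margin", "beta"
                        ),
                        zeta = 1, theta = 0.9,
                        similarity = c("inner", "pearson"),
                        fixed_len_s = NULL, overhead_s = 0) {
  name <- match.arg(name)
  similarity <- match.arg(similarity)
  structure(
    list(
      name = name, zeta = zeta, theta = theta, similarity = similarity,
      fixed_len_s = fixed_len_s, overhead_s = overhead_s
    ),
    class = "method_spec"
  )
}

# Build the fold's stopping rule from a method spec (training data only).
build_rule <- function(spec, trials, labels, fit, grid, seed = NULL) {
  switch(spec$name,
    "bds" = calibrate_bds(trials, labels, fit, grid = grid, zeta = spec$zeta),
    "fixed" = {
      len <- if (is.null(spec$fixed_len_s)) {
        max(grid)
      } else {
        sec_to_samples(spec$fixed_len_s, fit$sample_rate)
      }
      list(type = "fixed", window = which.min(abs(grid - len)))
    },
    "static-acc" = ,
    "static-target" = ,
    "static-itr" = {
      curve <- decoding_curve(
        trials, labels,
        structures_from_fit(fit), grid,
        similarity = spec$similarity, sample_rate = fit$sample_rate,
        seed = seed
      )
      criterion <- switch(spec$name,
        "static-acc" = "max-accuracy",
        "static-target" = "targeted",
        "static-itr" = "max-itr"
      )
      static_rule(curve, criterion, nrow(fit$templates),
        theta = spec$theta, overhead_s = spec$overhead_s
      )
    },
    "margin" = {
      streams <- lapply(seq_len(dim(trials)[1]), function(k) {
        score_stream(trials[k, , ], fit$w, fit$templates, grid, spec$similarity)
      })
      calibrate_margin(streams, labels, spec$theta)
    },
    "beta" = list(type = "beta", theta = spec$theta)
  )
}

# decoding_curve needs the structure matrices; carry them on the fit.
structures_from_fit <- function(fit) {
  st <- fit$structures
  if (is.null(st)) stop_invalid("fit carries no structure matrices")
  st
}

#' Cross-validated evaluation of a stopping method
#'
#' Stratified k-fold cross-validation on a simulated (or otherwise packaged)
#' dataset: per fold, the reconvolution CCA decoder and the stopping rule are
#' calibrated on the training split and every test trial is decoded on the
#' decision grid, logging all per-window decisions. Metrics per fold:
#' accuracy of the emitted classifications, mean stopping time, precision,
#' recall, specificity, F-score, and ITR at the mean stopping time.
#'
#' @param dataset A [simulate_dataset()] result (fields `trials`, `labels`,
#'   `structures`, `sample_rate`).
#' @param spec A [method_spec()].
#' @param n_folds Number of folds (default 5).
#' @param grid Decision grid in samples (default: 100 ms steps).
#' @param seed Seed for the fold assignment.
#' @param forced_positive Whether forced stops count as positive decisions.
#' @return A `cv_result`: list with `metrics` (per-fold tibble), `summary`
#'   (one-row tibble of across-fold means), and `log` (the pooled
#'   `decision_log`).
#' @export
crossvalidate <- function(dataset, spec, n_folds = 5, grid = NULL,
                          seed = 1L, forced_positive = TRUE) {
  if (!inherits(spec, "method_spec")) stop_invalid("`spec` must be a method_spec")
  trials <- dataset$trials
  labels <- dataset$labels
  K <- dim(trials)[1]
  if (K < n_folds) stop_invalid("fewer trials than folds")
  T_len <- dim(trials)[3]
  grid <- as.integer(grid %||% default_grid(T_len, dataset$sample_rate))
  folds <- stratified_folds(labels, n_folds, seed)
  fold_rows <- vector("list", n_folds)
  logs <- vector("list", n_folds)
  for (fo in seq_len(n_folds)) {
    tr <- folds != fo
    fit <- fit_rcca(trials[tr, , , drop = FALSE], labels[tr], dataset$structures)
    fit$structures <- dataset$structures
    rule <- build_rule(
      spec, trials[tr, , , drop = FALSE], labels[tr], fit, grid,
      seed = seed + fo
    )
    te <- which(!tr)
    log <- decode_trials(
      trials[te, , , drop = FALSE], labels[te], fit, rule, grid,
      similarity = spec$similarity
    )
    log$fold <- fo
    logs[[fo]] <- log
    fold_rows[[fo]] <- log_metrics(log, spec, dataset, forced_positive) |>
      dplyr::mutate(fold = fo, .before = 1L)
  }
  metrics <- dplyr::bind_rows(fold_rows)
  summary <- metrics |>
    dplyr::summarise(dplyr::across(-"fold", mean))
  structure(
    list(metrics = metrics, summary = summary, log = dplyr::bind_rows(logs)),
    class = "cv_result"
  )
}

log_metrics <- function(log, spec, dataset, forced_positive = TRUE) {
  stops <- log[log$accepted, ]
  counts <- suppressMessages(confusion_counts(log, forced_positive))
  accuracy <- mean(stops$predicted == stops$true_label)
  mean_stop <- mean(stops$time_s)
  tibble::tibble(
    accuracy = accuracy,
    mean_stop_time = mean_stop,
    precision = suppressMessages(precision(counts)),
    recall = suppressMessages(recall(counts)),
    specificity = suppressMessages(specificity(counts)),
    f_score = suppressMessages(f_score(counts)),
    itr = itr(accuracy, length(dataset$structures), mean_stop, spec$overhead_s)
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> across-fold means:\n")
  print(x$summary)
  invisible(x)
}

#' Hyper-parameter sweep of a stopping method
#'
#' Runs [crossvalidate()] at each hyper-parameter value — the cost ratio for
#' the Bayesian rule, the targeted accuracy for the baselines — and collects
#' one averaged metrics row per value, the material of accuracy-versus-time
#' and precision-versus-time operating curves.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param method Method name, see [method_spec()].
#' @param hyper_values Numeric vector of hyper-parameter values.
#' @param n_folds,grid,seed,forced_positive Passed to [crossvalidate()].
#' @param ... Further [method_spec()] fields (e.g. `similarity`).
#' @return A `stopping_sweep` tibble: `method`, `hyper`, and the averaged
#'   metrics columns.
#' @export
sweep_stopping <- function(dataset, method, hyper_values, n_folds = 5,
                           grid = NULL, seed = 1L, forced_positive = TRUE,
                           ...) {
  if (length(hyper_values) == 0L) stop_invalid("empty hyper-parameter grid")
  rows <- lapply(hyper_values, function(h) {
    spec <- if (method == "bds") {
      method_spec(method, zeta = h, ...)
    } else {
      method_spec(method, theta = h, ...)
    }
    cv <- crossvalidate(dataset, spec,
      n_folds = n_folds, grid = grid,
      seed = seed, forced_positive = forced_positive
    )
    dplyr::mutate(cv$summary, method = method, hyper = h, .before = 1L)
  })
  structure(
    dplyr::bind_rows(rows),
    class = c("stopping_sweep", class(tibble::tibble()))
  )
}
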