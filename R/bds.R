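#' Estimate the score-model scale and noise from calibration data
#'
#' Under the generative model `x = alpha * t_y + eps`, the scale factor is the
#' least-squares coefficient of the concatenated spatially filtered trials on
#' the concatenated label-matched templates, `alpha = (t.x) / (t.t)`, and the
#' noise level `sigma` is the standard deviation of the residual
#' `x - alpha * t` (population convention, divide by n; at calibration scale
#' the ddof choice is negligible but is fixed for bit-reproducibility).
#'
#' A negative `alpha` (anticorrelated projection) is allowed but flagged with
#' a warning, since the decoder's sign convention should prevent it.
#'
#' @param x Concatenated projected (virtual-channel) data.
#' @param tmpl Concatenated templates for the true labels, same length.
#' @return List with `alpha` and `sigma`.
#' @export
estimate_alpha_sigma <- function(x, tmpl) {
  x <- as.numeric(x)
  tmpl <- as.numeric(tmpl)
  if (length(x) != length(tmpl)) {
    stop_invalid("data and templates must have equal length")
  }
  tt <- sum(tmpl^2)
  if (tt == 0) stop_invalid("matched templates are identically zero")
  alpha <- sum(tmpl * x) / tt
  if (alpha < 0) {
    warn(sprintf("estimated alpha is negative (%.4g); check the filter sign convention", alpha))
  }
  resid <- x - alpha * tmpl
  sigma <- sqrt(mean((resid - mean(resid))^2))
  list(alpha = alpha, sigma = sigma)
}

#' Target and non-target score-distribution parameters at one window length
#'
#' With templates truncated to `window_len` samples, computes the multi-class
#' one-versus-rest Gaussian parameters of the inner-product score model:
#' \deqn{b_1 = \frac{1}{N}\sum_i \|t_i\|^2, \qquad
#'       b_0 = \frac{1}{N^2-N}\sum_i\sum_{j\ne i} t_i^\top t_j}
#' \deqn{\sigma_1^2 = \sigma^2 b_1 + \frac{1}{N}\sum_i (\alpha t_i^\top t_i - \alpha b_1)^2}
#' \deqn{\sigma_0^2 = \sigma^2 b_1 + \frac{1}{N^2-N}\sum_i\sum_{j\ne i}
#'       (\alpha t_i^\top t_j - \alpha b_0)^2}
#' The target score mean is `alpha * b1`, the non-target mean `alpha * b0`.
#'
#' @param templates `n_classes x T` template matrix.
#' @param window_len Truncation length in samples.
#' @param alpha,sigma Scale factor and noise standard deviation.
#' @return List with `b1`, `b0`, `var1`, `var0`, `alpha`, `sigma`,
#'   `window_len`.
#' @export
class_distribution_params <- function(templates, window_len, alpha, sigma) {
  tm <- as.matrix(templates)
  N <- nrow(tm)
  if (N < 2L) stop_invalid("at least 2 classes are required")
  if (window_len < 1L || window_len > ncol(tm)) {
    stop_invalid("window_len out of range")
  }
  tw <- tm[, seq_len(window_len), drop = FALSE]
  G <- tcrossprod(tw) # Gram matrix of truncated templates
  diag_g <- diag(G)
  off <- G
  diag(off) <- NA_real_
  off <- off[!is.na(off)]
  b1 <- mean(diag_g)
  b0 <- sum(off) / (N^2 - N)
  var1 <- sigma^2 * b1 + mean((alpha * diag_g - alpha * b1)^2)
  var0 <- sigma^2 * b1 + sum((alpha * off - alpha * b0)^2) / (N^2 - N)
  list(
    b1 = b1, b0 = b0, var1 = var1, var0 = var0,
    alpha = alpha, sigma = sigma, window_len = as.integer(window_len)
  )
}

#' Log likelihood ratio of the target vs non-target score model
#'
#' Direct Gaussian form: the log of the ratio of the target density
#' `N(alpha*b1, sigma1)` to the non-target density `N(alpha*b0, sigma0)` at
#' score `f`. This is the reference against which the quadratic decision form
#' is verified.
#'
#' @param f Score value(s).
#' @param p Distribution parameters from [class_distribution_params()].
#' @return Numeric log likelihood ratio(s).
#' @export
log_likelihood_ratio <- function(f, p) {
  if (p$var1 <= 0 || p$var0 <= 0) {
    stop_invalid("variances must be positive")
  }
  stats::dnorm(f, p$alpha * p$b1, sqrt(p$var1), log = TRUE) -
    stats::dnorm(f, p$alpha * p$b0, sqrt(p$var0), log = TRUE)
}

#' Coefficients of the quadratic Bayes-test form
#'
#' The likelihood-ratio test `ln Lambda(f) > ln((N-1) * zeta)` (equal class
#' priors merged into the target/non-target prior ratio `N - 1`; cost ratio
#' `zeta = c10/c01` with zero cost for correct decisions) is equivalent to
#' `a f^2 + b f + c > 0` with
#' \deqn{a = \sigma_1^2 - \sigma_0^2}
#' \deqn{b = -2\alpha(\sigma_1^2 b_0 - \sigma_0^2 b_1)}
#' \deqn{c = -\alpha^2(\sigma_0^2 b_1^2 - \sigma_1^2 b_0^2)
#'       + 2\sigma_0^2\sigma_1^2 \ln\frac{\sigma_0}{\sigma_1 (N-1)\zeta}}
#'
#' @param p Distribution parameters from [class_distribution_params()].
#' @param zeta Cost ratio (false-positive over false-negative cost), > 0.
#' @param n_classes Number of classes N (>= 2).
#' @return List with `a`, `b`, `c`, `zeta`, `n_classes`.
#' @export
quadratic_coefficients <- function(p, zeta, n_classes) {
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta) || zeta <= 0) {
    stop_invalid("`zeta` must be a positive finite number")
  }
  if (n_classes < 2L) stop_invalid("`n_classes` must be >= 2")
  s0 <- sqrt(p$var0)
  s1 <- sqrt(p$var1)
  a <- p$var1 - p$var0
  b <- -2 * p$alpha * (p$var1 * p$b0 - p$var0 * p$b1)
  cc <- -p$alpha^2 * (p$var0 * p$b1^2 - p$var1 * p$b0^2) +
    2 * p$var0 * p$var1 * log(s0 / (s1 * (n_classes - 1) * zeta))
  list(a = a, b = b, c = cc, zeta = zeta, n_classes = as.integer(n_classes))
}

#' Minimum-risk decision boundary from the quadratic coefficients
#'
#' Returns the root `eta = (-b + sqrt(b^2 - 4ac)) / (2a)` of the Bayes-test
#' quadratic — the larger root when `a > 0`, which is the operative
#' single-threshold boundary (scores above `eta` are accepted; the lower
#' root's pathological acceptance region at very negative scores is ignored).
#' When `a < 0` the same branch is used and a diagnostic is emitted, since the
#' acceptance region is then an interval but the test is specified as a single
#' threshold. Near-degenerate quadratics fall back to the linear solution
#' `eta = -c / b`; complex roots yield the sentinels `-Inf` (quadratic
#' everywhere positive: always accept) or `+Inf` (never accept).
#'
#' @param q Coefficients from [quadratic_coefficients()].
#' @param tol Relative tolerance deciding when `a` is treated as zero.
#' @return The boundary `eta` (possibly `-Inf`/`+Inf`).
#' @export
decision_boundary <- function(q, tol = 1e-12) {
  a <- q$a
  b <- q$b
  cc <- q$c
  if (!all(is.finite(c(a, b, cc)))) stop_invalid("coefficients must be finite")
  scale_bc <- abs(b) + abs(cc)
  if (abs(a) < tol * scale_bc) {
    if (abs(b) < tol * max(abs(cc), 1)) {
      abort("degenerate stopping model: both a and b vanish",
        class = "bdstop_degenerate_model"
      )
    }
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    # no real root: the quadratic never changes sign
    return(if (a > 0) -Inf else Inf)
  }
  if (a < 0) {
    inform(sprintf(
      "a = %.3g < 0: acceptance region is an interval; using the single-threshold branch",
      a
    ))
  }
  (-b + sqrt(disc)) / (2 * a)
}

#' Calibrate a Bayesian dynamic stopping model
#'
#' Runs the five calibration steps: spatially filter and concatenate the
#' training trials, estimate `(alpha, sigma)` once from the full-length
#' least-squares fit against the label-matched templates, then per decision
#' window compute the target/non-target Gaussian parameters and the
#' minimum-risk boundary `eta`.
#'
#' @param trials `K x C x T` training array.
#' @param labels Class labels (1-based), length K.
#' @param model An [fit_rcca()] fit supplying the spatial filter and
#'   templates (alternatively pass `w` and `templates` explicitly).
#' @param grid Increasing decision-window lengths in samples; the last entry
#'   is the forced-stop length `t*`. Default: 100 ms steps up to the full
#'   trial length.
#' @param zeta Cost ratio controlling the precision/speed balance.
#' @param w,templates Optional explicit spatial filter and template matrix.
#' @param per_window Re-estimate `(alpha, sigma)` at each window length
#'   instead of once at full length (default `FALSE`).
#' @return A `bds_model`: list with `grid`, per-window `params`, `eta`,
#'   `alpha`, `sigma`, `zeta`, `n_classes`, `max_len`, `sample_rate`.
#' @export
calibrate_bds <- function(trials, labels, model = NULL, grid = NULL,
                          zeta = 1, w = NULL, templates = NULL,
                          per_window = FALSE) {
  if (!is.null(model)) {
    w <- w %||% model$w
    templates <- templates %||% model$templates
  }
  if (is.null(w) || is.null(templates)) {
    stop_invalid("supply a fitted decoder or explicit `w` and `templates`")
  }
  tm <- as.matrix(templates)
  T_len <- ncol(tm)
  sample_rate <- attr(templates, "sample_rate") %||% NA_real_
  if (is.null(grid)) grid <- default_grid(T_len, sample_rate)
  grid <- as.integer(grid)
  if (any(diff(grid) <= 0L) || grid[1] < 1L || max(grid) > T_len) {
    stop_invalid("`grid` must be strictly increasing within (0, T]")
  }
  labels <- as.integer(labels)

  proj <- t(vapply(
    seq_len(dim(trials)[1]),
    function(k) project_trial(trials[k, , ], w),
    numeric(T_len)
  ))
  x_cat <- as.numeric(t(proj))
  t_cat <- as.numeric(t(tm[labels, , drop = FALSE]))
  est <- estimate_alpha_sigma(x_cat, t_cat)

  N <- nrow(tm)
  params <- lapply(grid, function(s) {
    if (per_window) {
      keep <- as.numeric(vapply(
        seq_len(nrow(proj)),
        function(k) proj[k, seq_len(s)], numeric(s)
      ))
      tk <- as.numeric(vapply(
        seq_len(nrow(proj)),
        function(k) tm[labels[k], seq_len(s)], numeric(s)
      ))
      ew <- estimate_alpha_sigma(keep, tk)
      class_distribution_params(tm, s, ew$alpha, ew$sigma)
    } else {
      class_distribution_params(tm, s, est$alpha, est$sigma)
    }
  })
  eta <- vapply(
    params,
    function(p) decision_boundary(quadratic_coefficients(p, zeta, N)),
    numeric(1)
  )
  structure(
    list(
      grid = grid, params = params, eta = eta,
      alpha = est$alpha, sigma = est$sigma, zeta = zeta,
      n_classes = N, max_len = max(grid), sample_rate = sample_rate,
      w = w, templates = tm
    ),
    class = "bds_model"
  )
}

#' Recompute the decision boundaries of a calibrated model for a new cost ratio
#'
#' The cost ratio enters only the constant coefficient of the Bayes-test
#' quadratic, so sweeping it requires no re-estimation of the distribution
#' parameters.
#'
#' @param model A `bds_model`.
#' @param zeta New cost ratio.
#' @return The model with updated `eta` and `zeta`.
#' @export
update_zeta <- function(model, zeta) {
  model$eta <- vapply(
    model$params,
    function(p) decision_boundary(quadratic_coefficients(p, zeta, model$n_classes)),
    numeric(1)
  )
  model$zeta <- zeta
  model
}

# Default decision grid: 100 ms steps from 100 ms to the full trial length.
default_grid <- function(T_len, sample_rate, step_s = 0.1) {
  if (is.na(sample_rate)) {
    stop_invalid("cannot build a default grid without a sample rate")
  }
  step <- sec_to_samples(step_s, sample_rate)
  g <- seq(step, T_len, by = step)
  if (max(g) < T_len) g <- c(g, T_len)
  as.integer(g)
}

#' @export
print.bds_model <- function(x, ...) {
  cat(sprintf(
    "<bds_model> N = %d classes, %d decision windows up to %d samples, zeta = %g\n  alpha = %.4g, sigma = %.4g, eta range [%.4g, %.4g]\n",
    x$n_classes, length(x$grid), x$max_len, x$zeta, x$alpha, x$sigma,
    min(x$eta), max(x$eta)
  ))
  invisible(x)
}

#' Run the Bayesian stopping procedure on a stream of score vectors
#'
#' At each decision window the per-class inner-product scores are compared
#' with that window's boundary `eta`. The trial stops at the first window
#' where any score exceeds `eta`, emitting the passing class with the highest
#' likelihood of being the target. In the usual `a > 0` regime the log
#' likelihood ratio is increasing above `eta`, so the highest-likelihood
#' passing class is the argmax score; the same single-threshold ordering is
#' kept in the pathological `a < 0` regime for consistency with the
#' single-threshold stopping test itself. If no window passes, the trial is
#' force-stopped at the maximum length `t*` and the argmax class emitted.
#'
#' @param scores `n_windows x n_classes` matrix of inner-product scores, rows
#'   aligned with `model$grid` (e.g. from the internal score stream of
#'   [decode_trials()]).
#' @param model A `bds_model`.
#' @return A `stopping_decision`: list with `stop_window`, `stop_time`
#'   (seconds, `NA` if the sample rate is unknown), `predicted`, `forced`,
#'   and `score_trace` (the visited rows of `scores`).
#' @export
decide_bds <- function(scores, model) {
  scores <- as.matrix(scores)
  if (nrow(scores) == 0L) stop_invalid("empty score stream")
  if (nrow(scores) != length(model$grid)) {
    stop_invalid("score stream must have one row per decision window")
  }
  n_win <- nrow(scores)
  for (jw in seq_len(n_win)) {
    f <- scores[jw, ]
    pass <- which(f > model$eta[jw])
    last <- jw == n_win
    if (length(pass) > 0L || last) {
      if (length(pass) > 0L) {
        predicted <- pass[classify(f[pass])]
        forced <- FALSE
      } else {
        predicted <- classify(f)
        forced <- TRUE
      }
      return(new_stopping_decision(
        stop_window = jw,
        stop_time = samples_to_sec(model$grid[jw], model$sample_rate),
        predicted = predicted, forced = forced,
        score_trace = scores[seq_len(jw), , drop = FALSE]
      ))
    }
  }
}

new_stopping_decision <- function(stop_window, stop_time, predicted, forced,
                                  score_trace) {
  structure(
    list(
      stop_window = as.integer(stop_window), stop_time = stop_time,
      predicted = as.integer(predicted), forced = forced,
      score_trace = score_trace
    ),
    class = "stopping_decision"
  )
}

#' @export
print.stopping_decision <- function(x, ...) {
  cat(sprintf(
    "<stopping_decision> class %d at window %d (%.3g s)%s\n",
    x$predicted, x$stop_window, x$stop_time,
    if (x$forced) " [forced]" else ""
  ))
  invisible(x)
}

#' @rdname glance.bds_model
#' @method tidy bds_model
#' @export
tidy.bds_model <- function(x, ...) {
  tibble::tibble(
    window = seq_along(x$grid),
    window_len = x$grid,
    time_s = samples_to_sec(x$grid, x$sample_rate),
    b1 = vapply(x$params, `[[`, numeric(1), "b1"),
    b0 = vapply(x$params, `[[`, numeric(1), "b0"),
    mean_target = x$alpha * vapply(x$params, `[[`, numeric(1), "b1"),
    mean_nontarget = x$alpha * vapply(x$params, `[[`, numeric(1), "b0"),
    sd_target = sqrt(vapply(x$params, `[[`, numeric(1), "var1")),
    sd_nontarget = sqrt(vapply(x$params, `[[`, numeric(1), "var0")),
    eta = x$eta
  )
}

#' Broom-style accessors for Bayesian stopping models
#'
#' `tidy()` returns one row per decision window with the Gaussian parameters
#' of the target/non-target score distributions and the boundary `eta`;
#' `glance()` returns a one-row summary of the calibrated model.
#'
#' @param x A `bds_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method glance bds_model
#' @export
glance.bds_model <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, sigma = x$sigma, zeta = x$zeta,
    n_classes = x$n_classes, n_windows = length(x$grid),
    max_len = x$max_len, sample_rate = x$sample_rate
  )
}
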