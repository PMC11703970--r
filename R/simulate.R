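#' Simulation configuration for synthetic c-VEP trials
#'
#' Bundles the generative-model settings for [simulate_dataset()]. Defaults
#' emulate the 6x6 matrix-speller geometry this package targets: 36 classes tagged with
#' 126-frame two-duration-modulated degree-6 Gold codes at 120 Hz, 4 code
#' cycles per trial (4.2 s), 3 repetitions per class (108 trials).
#'
#' The generative model is `x = alpha * t_y + eps` on a virtual source
#' channel, with `eps` iid Gaussian noise of standard deviation `sigma`; the
#' source is embedded into `n_channels` EEG channels through a fixed random
#' unit-norm spatial pattern plus iid background noise (`sigma_bg`).
#'
#' @param n_classes Number of stimulus classes N.
#' @param n_reps Repetitions of each class.
#' @param n_channels EEG channels C.
#' @param sample_rate Sampling rate in Hz (default 120, one sample per frame).
#' @param n_cycles Code cycles per trial.
#' @param alpha Source scale factor.
#' @param sigma Source noise standard deviation. The default gives roughly
#'   80% single-cycle (1.05 s) decoding accuracy under the default kernel —
#'   a moderate-SNR operating point.
#' @param sigma_bg Per-channel background noise standard deviation (defaults
#'   to `sigma`).
#' @param response_len_s Temporal response length per event kind, seconds.
#' @param kernel_spec Damped-sinusoid parameters per event kind: a list with
#'   `short` and `long`, each `list(amplitude, freq_hz, decay)` (decay in 1/s).
#' @param frame_rate Base (pre-modulation) code rate in Hz.
#' @param seed RNG seed; noise and the spatial pattern are the only
#'   stochastic elements.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_classes = 36, n_reps = 3, n_channels = 8,
                       sample_rate = 120, n_cycles = 4,
                       alpha = 1, sigma = 1.1, sigma_bg = sigma,
                       response_len_s = 0.3,
                       kernel_spec = default_kernel_spec(),
                       frame_rate = 60, seed = 1L) {
  assert_scalar_number(n_classes, "n_classes", 2, Inf)
  assert_scalar_number(n_channels, "n_channels", 1, Inf)
  assert_scalar_number(alpha, "alpha", 0, Inf)
  assert_scalar_number(sigma, "sigma", 0, Inf)
  assert_scalar_number(sigma_bg, "sigma_bg", 0, Inf)
  structure(
    list(
      n_classes = as.integer(n_classes), n_reps = as.integer(n_reps),
      n_channels = as.integer(n_channels), sample_rate = sample_rate,
      n_cycles = as.integer(n_cycles), alpha = alpha, sigma = sigma,
      sigma_bg = sigma_bg, response_len_s = response_len_s,
      kernel_spec = kernel_spec, frame_rate = frame_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

default_kernel_spec <- function() {
  list(
    short = list(amplitude = 1.0, freq_hz = 12, decay = 8),
    long = list(amplitude = 0.8, freq_hz = 9, decay = 6)
  )
}

#' Ground-truth temporal response kernel
#'
#' Deterministic damped sinusoid per event kind,
#' `A * sin(2 pi f t) * exp(-decay * t)`, sampled at `sample_rate` and
#' concatenated in structure-row order (short flash first, then long flash).
#'
#' @param kernel_spec See [sim_config()].
#' @param response_len Samples per event kind.
#' @param sample_rate Hz.
#' @return Numeric vector of length `2 * response_len`.
#' @export
ground_truth_response <- function(kernel_spec, response_len, sample_rate) {
  if (response_len < 1L) stop_invalid("response_len must be >= 1")
  tt <- (seq_len(response_len) - 1L) / sample_rate
  unlist(lapply(kernel_spec[c("short", "long")], function(k) {
    k$amplitude * sin(2 * pi * k$freq_hz * tt) * exp(-k$decay * tt)
  }), use.names = FALSE)
}

#' Simulate one multichannel trial
#'
#' Draws the virtual source `s = alpha * t_y + eps` with iid Gaussian noise,
#' then embeds it as `X = pattern %o% s + background`, with iid Gaussian
#' background noise per channel. When the background noise is finite a
#' spatial filter recovering `s` up to scale exists (the pattern itself).
#'
#' @param class_y True class index (1-based).
#' @param config A `sim_config`.
#' @param templates Source `template_set` built from the config's codes and
#'   kernel.
#' @param pattern Unit-norm spatial pattern (length `n_channels`).
#' @return `C x T` numeric matrix.
#' @export
simulate_trial <- function(class_y, config, templates, pattern) {
  tm <- as.matrix(templates)
  if (class_y < 1L || class_y > nrow(tm)) {
    stop_invalid("invalid class index %s", class_y)
  }
  T_len <- ncol(tm)
  s <- config$alpha * tm[class_y, ] + stats::rnorm(T_len, 0, config$sigma)
  X <- outer(pattern, s)
  if (config$sigma_bg > 0) {
    X <- X + matrix(
      stats::rnorm(length(pattern) * T_len, 0, config$sigma_bg),
      nrow = length(pattern)
    )
  }
  X
}

#' Simulate a full synthetic c-VEP dataset with known ground truth
#'
#' Generates the default Gold code family, modulates it, selects the
#' `n_classes` lowest-correlation codes by template correlation, builds
#' structure matrices and source templates from the ground-truth kernel, and
#' simulates `n_classes * n_reps` trials in randomized order.
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset`: list with `trials` (`K x C x T`), `labels`,
#'   `codes` (modulated `code_set` for the selected classes), `structures`,
#'   `sample_rate`, `config`, and `ground_truth` (spatial pattern, temporal
#'   response, source templates, `alpha`, `sigma`, `sigma_bg`, and
#'   `sigma_virtual` — the noise level recoverable on a unit-norm
#'   spatially filtered virtual channel, `sqrt(sigma^2 + sigma_bg^2)`).
#' @examples
#' ds <- simulate_dataset(sim_config(n_classes = 4, n_reps = 2, seed = 7))
#' dim(ds$trials) # 8 x 8 x 504
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  codes_all <- modulate(gold_code_family(
    default_preferred_pair()$u, default_preferred_pair()$v,
    frame_rate = config$frame_rate
  ))
  response_len <- sec_to_samples(config$response_len_s, config$sample_rate)
  structs_all <- structure_matrices(
    codes_all,
    sample_rate = config$sample_rate,
    response_len = response_len, n_cycles = config$n_cycles
  )
  kernel <- ground_truth_response(
    config$kernel_spec, response_len, config$sample_rate
  )
  templates_all <- predict_templates(kernel, structs_all)
  sel <- select_subset(templates_all, config$n_classes)
  codes <- code_set(unclass(codes_all)[sel, , drop = FALSE],
    frame_rate = attr(codes_all, "frame_rate"), modulated = TRUE
  )
  structures <- structs_all[sel]
  templates <- structure(
    as.matrix(templates_all)[sel, , drop = FALSE],
    sample_rate = config$sample_rate,
    class = c("template_set", "matrix", "array")
  )

  pattern <- stats::rnorm(config$n_channels)
  if (pattern[which.max(abs(pattern))] < 0) pattern <- -pattern
  pattern <- pattern / sqrt(sum(pattern^2))

  K <- config$n_classes * config$n_reps
  labels <- sample(rep(seq_len(config$n_classes), config$n_reps))
  T_len <- ncol(templates)
  trials <- array(0, dim = c(K, config$n_channels, T_len))
  for (k in seq_len(K)) {
    trials[k, , ] <- simulate_trial(labels[k], config, templates, pattern)
  }
  structure(
    list(
      trials = trials, labels = labels, codes = codes,
      structures = structures, sample_rate = config$sample_rate,
      config = config,
      ground_truth = list(
        spatial_pattern = pattern, temporal_response = kernel,
        templates = templates, alpha = config$alpha, sigma = config$sigma,
        sigma_bg = config$sigma_bg,
        sigma_virtual = sqrt(config$sigma^2 + config$sigma_bg^2),
        selected_codes = sel
      )
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<sim_dataset> %d trials x %d channels x %d samples (%g s at %g Hz), %d classes\n",
    d[1], d[2], d[3], d[3] / x$sample_rate, x$sample_rate,
    x$config$n_classes
  ))
  invisible(x)
}
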