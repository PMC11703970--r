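#' @importFrom rlang abort warn inform %||%
#' @importFrom stats cor optim pnorm dnorm qnorm rnorm sd pbeta dbeta qbinom
#' @importFrom utils head tail
NULL

# Stop with a classed condition so callers/tests can distinguish user errors.
stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "bdstop_invalid_argument")
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop_invalid("`%s` must be a single finite number in [%s, %s]", name, min, max)
  }
  invisible(x)
}

is_binary <- function(x) all(x %in% c(0, 1))

# seconds <-> samples conversion, centralized (half-open windows, 0-based onsets)
sec_to_samples <- function(t_sec, sample_rate) as.integer(round(t_sec * sample_rate))
samples_to_sec <- function(n, sample_rate) n / sample_rate

# Stratified fold assignment: within each class, trials are dealt out to
# folds in a seeded random order; best-effort when classes are smaller than
# the number of folds.
stratified_folds <- function(labels, n_folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    # deal this class's trials across a fresh random fold order so classes
    # with fewer trials than folds still spread over all folds
    ord <- sample(n_folds)
    folds[idx] <- ord[((seq_along(idx) - 1L) %% n_folds) + 1L]
  }
  folds
}

# Maximal runs of ones in a binary vector: tibble-free internal helper.
# Returns list(start = 1-based start indices, length = run lengths).
runs_of_ones <- function(bits) {
  r <- rle(as.integer(bits))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  list(start = starts[keep], length = r$lengths[keep])
}
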