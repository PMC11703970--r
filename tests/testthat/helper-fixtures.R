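# Shared fixtures, built once per test run. All synthetic: no stored data.

# Small 6-class dataset at the default (moderate) SNR.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(
        sim_config(n_classes = 6, n_reps = 6, n_channels = 4, seed = 101)
      )
    }
    cache
  }
})

# Noise-free 4-class dataset (sigma = sigma_bg = 0).
noiseless_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(
        n_classes = 4, n_reps = 3, n_channels = 3,
        sigma = 0, sigma_bg = 0, seed = 7
      ))
    }
    cache
  }
})

# Hand-sized template set with two toy structure matrices for arithmetic tests.
toy_structures <- function() {
  # 8-sample trials, response_len 2, single event kind placement by hand
  mk <- function(onsets_short, onsets_long = integer(0), T_len = 8L, R = 2L) {
    M <- matrix(0L, 2L * R, T_len)
    for (o in onsets_short) for (m in 0:(R - 1L)) {
      if (o + m < T_len) M[m + 1L, o + m + 1L] <- 1L
    }
    for (o in onsets_long) for (m in 0:(R - 1L)) {
      if (o + m < T_len) M[R + m + 1L, o + m + 1L] <- 1L
    }
    structure(M, response_len = R, sample_rate = 8, class = c("structure_matrix", "matrix", "array"))
  }
  list(mk(c(0L, 4L)), mk(2L, 5L), mk(integer(0), c(1L, 6L)))
}

# Distribution parameters drawn from realistic random template sets; always
# valid (positive variances), moderately separated.
random_params <- function(n_classes = NULL, window_len = 24L) {
  N <- n_classes %||% sample(3:12, 1)
  tm <- matrix(rnorm(N * window_len), N)
  alpha <- runif(1, 0.3, 2)
  sigma <- runif(1, 0.3, 2)
  class_distribution_params(tm, window_len, alpha, sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
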