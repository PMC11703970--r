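test_that("decoding curves hit the noise-free ceiling and chance floor", {
  ds <- noiseless_dataset()
  grid <- c(63L, 126L, 252L, 504L)
  curve <- decoding_curve(ds$trials, ds$labels, ds$structures, grid,
    n_folds = 3, seed = 1
  )
  expect_equal(nrow(curve), length(grid))
  expect_equal(curve$accuracy, rep(1, 4))

  # alpha = 0: no signal, accuracy at chance within binomial error
  ds0 <- simulate_dataset(sim_config(
    n_classes = 6, n_reps = 30, n_channels = 4, alpha = 0, seed = 61
  ))
  curve0 <- decoding_curve(ds0$trials, ds0$labels, ds0$structures,
    grid = c(126L, 504L), n_folds = 5, seed = 2
  )
  n <- length(ds0$labels)
  ci <- qbinom(c(0.005, 0.995), n, 1 / 6) / n
  expect_true(all(curve0$accuracy >= ci[1] & curve0$accuracy <= ci[2]))
})

test_that("static rules pick the specified windows from a curve", {
  curve <- tibble::tibble(
    window = 1:3, window_len = c(10L, 20L, 30L),
    time_s = c(1, 2, 3), accuracy = c(0.2, 0.9, 0.9)
  )
  expect_equal(static_rule(curve, "max-accuracy", 8)$stop_window, 2L)
  curve2 <- dplyr::mutate(curve, accuracy = c(0.2, 0.5, 0.8))
  expect_equal(static_rule(curve2, "targeted", 8, theta = 0.6)$stop_window, 3L)
  # unattainable target falls back to the max-accuracy window
  expect_equal(static_rule(curve2, "targeted", 8, theta = 0.95)$stop_window, 3L)
  # flat accuracy: ITR prefers the shorter window
  curve3 <- tibble::tibble(
    window = 1:2, window_len = c(10L, 20L), time_s = c(1, 2),
    accuracy = c(0.9, 0.9)
  )
  expect_equal(static_rule(curve3, "max-itr", 8)$stop_window, 1L)
  expect_gt(itr(0.9, 8, 1), itr(0.9, 8, 2))
  expect_error(static_rule(curve[0, ], "max-accuracy", 8),
    class = "bdstop_invalid_argument"
  )
})

test_that("margin thresholds achieve the targeted accuracy on training data", {
  # one window; margins/correctness (0.9, T), (0.5, F), (0.4, T)
  streams <- list(
    rbind(c(1.9, 1.0, 0)), # margin 0.9, argmax 1
    rbind(c(0.2, 0.7, 0.1)), # margin 0.5, argmax 2
    rbind(c(1.0, 0.6, 0.2)) # margin 0.4, argmax 1
  )
  labels <- c(1L, 1L, 1L) # trial 2 is misclassified
  rule <- calibrate_margin(streams, labels, theta = 1.0)
  expect_equal(rule$thresholds, 0.9)
  # exhaustive scan oracle over candidate thresholds
  margins <- c(0.9, 0.5, 0.4)
  correct <- c(TRUE, FALSE, TRUE)
  cands <- sort(margins)
  ref <- Inf
  for (m in cands) {
    if (mean(correct[margins >= m]) >= 1.0) {
      ref <- m
      break
    }
  }
  expect_equal(rule$thresholds, ref)
  # all-correct window: threshold is the smallest observed margin
  rule_ok <- calibrate_margin(streams, c(1L, 2L, 1L), theta = 1.0)
  expect_equal(rule_ok$thresholds, 0.4)
  # theta = 0: every training trial stops at the first window
  rule0 <- calibrate_margin(streams, labels, theta = 0)
  for (s in streams) {
    d <- apply_margin(s, rule0, grid = 10L, sample_rate = 10)
    expect_equal(d$stop_window, 1L)
    expect_false(d$forced)
  }
})

test_that("the margin rule replays as a brute-force threshold scan", {
  set.seed(70)
  grid <- c(5L, 10L, 15L, 20L)
  rule <- structure(
    list(thresholds = c(0.8, 0.5, Inf, 0.2), theta = 0.9),
    class = "margin_rule"
  )
  for (i in 1:100) {
    sc <- matrix(rnorm(4 * 5), 4)
    d <- apply_margin(sc, rule, grid, sample_rate = 10)
    # independent replay
    stop_ref <- NA
    for (jw in 1:4) {
      srt <- sort(sc[jw, ], decreasing = TRUE)
      if (srt[1] - srt[2] >= rule$thresholds[jw] || jw == 4) {
        stop_ref <- jw
        break
      }
    }
    expect_equal(d$stop_window, stop_ref)
    expect_equal(d$predicted, which.max(sc[stop_ref, ]))
  }
  # all-infinite thresholds: forced argmax at the maximum length
  rule_inf <- structure(
    list(thresholds = rep(Inf, 4), theta = 0.9),
    class = "margin_rule"
  )
  sc <- matrix(rnorm(20), 4)
  d <- apply_margin(sc, rule_inf, grid, sample_rate = 10)
  expect_equal(d$stop_window, 4L)
  expect_true(d$forced)
})

test_that("the Beta rule stops on outlying maxima and respects its bounds", {
  grid <- c(5L, 10L)
  # maximum mapped score 1.0: cumulative probability 1 beats any theta < 1
  sc_hit <- rbind(c(1, -0.2, 0.1, -0.5, 0.3), c(0, 0, 0, 0, 0))
  d <- apply_beta(sc_hit, theta = 0.95, grid, sample_rate = 10)
  expect_equal(d$stop_window, 1L)
  expect_equal(d$predicted, 1L)
  expect_false(d$forced)
  # theta = 1 with maximum < 1: never stops before the maximum length
  sc_low <- rbind(
    c(0.6, -0.2, 0.1, -0.5, 0.3),
    c(0.55, -0.1, 0.2, -0.4, 0.25)
  )
  d2 <- apply_beta(sc_low, theta = 1, grid, sample_rate = 10)
  expect_equal(d2$stop_window, 2L)
  expect_true(d2$forced)
  # degenerate all-equal scores never trigger a stop
  sc_flat <- rbind(c(0.5, 0.5, 0.5, 0.5, 0.5), c(0.9, 0, 0, 0, 0))
  d3 <- apply_beta(sc_flat, theta = 0.5, grid, sample_rate = 10)
  expect_equal(d3$stop_window, 2L)
  expect_error(apply_beta(sc_hit * 3, 0.9, grid), class = "bdstop_invalid_argument")
  expect_error(
    apply_beta(sc_hit[, 1:2, drop = FALSE], 0.9, grid),
    class = "bdstop_invalid_argument"
  )
})

test_that("the Beta fit matches an independent maximum-likelihood optimizer", {
  set.seed(71)
  x <- rbeta(35, 2.3, 4.1)
  fit <- bdstop:::fit_beta_ml(x)
  nll <- function(par) -sum(dbeta(x, exp(par[1]), exp(par[2]), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit$shape1, exp(opt$par[1]), tolerance = 1e-4)
  expect_equal(fit$shape2, exp(opt$par[2]), tolerance = 1e-4)
  expect_equal(
    -nll(log(c(fit$shape1, fit$shape2))), -opt$value,
    tolerance = 1e-6
  )
})

test_that("dynamic rules stop early at high SNR without losing accuracy", {
  theta <- 0.9
  ds <- simulate_dataset(sim_config(
    n_classes = 5, n_reps = 8, n_channels = 4, sigma = 0.05, seed = 72
  ))
  n <- length(ds$labels)
  fit <- fit_rcca(ds$trials, ds$labels, ds$structures)
  fit$structures <- ds$structures
  grid <- bdstop:::default_grid(dim(ds$trials)[3], ds$sample_rate)
  full_time <- max(grid) / ds$sample_rate
  # reference: fixed-length decoding at the full trial length
  log_full <- decode_trials(
    ds$trials, ds$labels, fit, list(type = "fixed", window = length(grid)), grid
  )
  acc_full <- with(log_full[log_full$accepted, ], mean(predicted == true_label))
  expect_equal(acc_full, 1.0)
  rules <- list(
    bds = calibrate_bds(ds$trials, ds$labels, fit, zeta = 1),
    margin = bdstop:::build_rule(
      method_spec("margin", theta = theta), ds$trials, ds$labels, fit, grid
    ),
    beta = list(type = "beta", theta = theta)
  )
  for (nm in names(rules)) {
    log <- suppressMessages(decode_trials(
      ds$trials, ds$labels, fit, rules[[nm]], grid,
      similarity = if (nm == "beta") "pearson" else "inner"
    ))
    stops <- log[log$accepted, ]
    acc <- mean(stops$predicted == stops$true_label)
    expect_lt(mean(stops$time_s), full_time / 2)
    if (nm == "margin") {
      # per-window thresholds are marginal, not sequential-conditional, so the
      # achieved accuracy tracks the targeted accuracy, not the ceiling
      expect_gte(acc, theta - 2 * sqrt(theta * (1 - theta) / n))
    } else {
      expect_gte(acc, acc_full - 2 * sqrt(0.05 * 0.95 / n))
    }
    # every emitted class is the argmax of the final score vector
    expect_equal(stops$predicted, stops$argmax)
    expect_true(all(stops$time_s >= grid[1] / ds$sample_rate))
    expect_true(all(stops$time_s <= full_time))
  }
})
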