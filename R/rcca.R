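#' Fit a reconvolution CCA decoder
#'
#' Learns a spatial filter `w` (one weight per EEG channel) and a temporal
#' response vector `r` (one kernel sample per structure-matrix row) from
#' labeled training trials. The trials are concatenated channel-wise into
#' `S` (channels x K*T) and their label-matched structure matrices stacked
#' into `D` (structure rows x K*T); canonical correlation analysis then finds
#' the `(w, r)` pair maximizing the Pearson correlation between the spatially
#' filtered EEG `w'S` and the reconvolved predicted response `r'D`.
#'
#' Covariance blocks are ridge-regularized (`lambda` scaled by the mean
#' diagonal of each block) because structure matrices are rank deficient at
#' short windows. Only the leading canonical pair is kept. The sign is fixed
#' so the canonical correlation is positive and the largest-magnitude filter
#' weight is positive; `w` is scaled to unit Euclidean norm and `r` carries
#' the remaining scale, so the physical response amplitude is absorbed
#' downstream by the stopping model's scale factor.
#'
#' @param trials Numeric array `K x C x T` (trials x channels x samples).
#' @param labels Integer class labels (1-based), length `K`.
#' @param structures List of per-class structure matrices (`M x T` each), see
#'   [structure_matrix()].
#' @param lambda Relative ridge strength for both covariance blocks.
#' @return An `rcca` object: list with `w` (length C), `r` (length M), `rho`
#'   (canonical correlation), `templates` (`n_classes x T` matrix, `r' M_i`
#'   per class), and `sample_rate` taken from the structures.
#' @export
fit_rcca <- function(trials, labels, structures, lambda = 1e-8) {
  if (length(dim(trials)) != 3L) {
    stop_invalid("`trials` must be a K x C x T array")
  }
  K <- dim(trials)[1]
  C <- dim(trials)[2]
  T_len <- dim(trials)[3]
  if (K < 2L) stop_invalid("at least 2 training trials are required")
  labels <- as.integer(labels)
  if (length(labels) != K) stop_invalid("`labels` must have one entry per trial")
  if (any(labels < 1L) || any(labels > length(structures))) {
    stop_invalid("labels must index `structures`")
  }
  if (any(vapply(structures, ncol, 1L) != T_len)) {
    stop_invalid("structure matrices must have T columns matching the trials")
  }
  M <- nrow(structures[[1]])

  S <- matrix(0, nrow = C, ncol = K * T_len)
  D <- matrix(0, nrow = M, ncol = K * T_len)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * T_len + 1L):(k * T_len)
    S[, idx] <- trials[k, , ]
    D[, idx] <- structures[[labels[k]]]
  }
  cca <- cca_leading_pair(S, D, lambda = lambda)
  w <- cca$w
  r <- cca$r

  # sign convention: positive canonical correlation, then positive
  # largest-magnitude filter weight (flipping w and r together preserves rho)
  if (stats::cor(drop(crossprod(w, S)), drop(crossprod(r, D))) < 0) r <- -r
  if (w[which.max(abs(w))] < 0) {
    w <- -w
    r <- -r
  }
  nw <- sqrt(sum(w^2))
  w <- w / nw
  r <- r / nw

  templates <- predict_templates(r, structures)
  structure(
    list(
      w = w, r = r, rho = cca$rho, templates = templates,
      sample_rate = attr(structures[[1]], "sample_rate") %||% NA_real_,
      n_channels = C, n_samples = T_len
    ),
    class = "rcca"
  )
}

# Leading canonical pair of row-variable matrices X (p x n) and Y (q x n)
# via whitened SVD on ridge-regularized covariance blocks.
cca_leading_pair <- function(X, Y, lambda = 1e-8) {
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  Cxx <- tcrossprod(Xc) / (n - 1)
  Cyy <- tcrossprod(Yc) / (n - 1)
  Cxy <- tcrossprod(Xc, Yc) / (n - 1)
  Cxx <- Cxx + diag(lambda * mean(diag(Cxx)) + 1e-300, nrow(Cxx))
  Cyy <- Cyy + diag(lambda * mean(diag(Cyy)) + 1e-300, nrow(Cyy))
  Rx <- chol(Cxx)
  Ry <- chol(Cyy)
  Kmat <- t(backsolve(Rx, Cxy, transpose = TRUE))
  Kmat <- t(backsolve(Ry, Kmat, transpose = TRUE)) # inv(Rx') Cxy inv(Ry)
  sv <- svd(Kmat, nu = 1L, nv = 1L)
  list(
    w = backsolve(Rx, sv$u[, 1L]),
    r = backsolve(Ry, sv$v[, 1L]),
    rho = sv$d[1L]
  )
}

#' @export
print.rcca <- function(x, ...) {
  cat(sprintf(
    "<rcca> %d channels, %d kernel samples, %d templates x %d samples, rho = %.4f\n",
    length(x$w), length(x$r), nrow(x$templates), ncol(x$templates), x$rho
  ))
  invisible(x)
}

#' Predict per-class template responses
#'
#' Applies a temporal response vector to each class's structure matrix:
#' template `t_i = r' M_i`, the reconvolved predicted single-channel evoked
#' response to stimulus `i`.
#'
#' @param r Temporal response vector (length M).
#' @param structures List of `M x T` structure matrices.
#' @return A `template_set`: `n_classes x T` numeric matrix with a
#'   `sample_rate` attribute.
#' @export
predict_templates <- function(r, structures) {
  r <- as.numeric(r)
  M <- nrow(structures[[1]])
  if (length(r) != M) {
    stop_invalid(
      "temporal response length (%d) must match structure rows (%d)",
      length(r), M
    )
  }
  tm <- t(vapply(
    structures,
    function(Mi) drop(crossprod(r, Mi)),
    numeric(ncol(structures[[1]]))
  ))
  structure(tm,
    sample_rate = attr(structures[[1]], "sample_rate") %||% NA_real_,
    class = c("template_set", "matrix", "array")
  )
}

#' Score one trial against all class templates
#'
#' Projects the trial through the spatial filter and compares the first
#' `window_len` samples with each truncated template. The inner product
#' (unnormalized dot product) is the similarity required by the Bayesian
#' stopping model; Pearson correlation is the conventional bounded
#' alternative.
#'
#' @param X Trial data, `C x T` matrix (or a length-T vector for
#'   already-filtered single-channel data with `w = NULL`).
#' @param w Spatial filter (length C), or `NULL` if `X` is already projected.
#' @param templates `template_set` (or matrix), `n_classes x T`.
#' @param window_len Decision window length in samples (`<= T`).
#' @param similarity `"inner"` or `"pearson"`.
#' @return Numeric vector of per-class scores with attributes `similarity`
#'   and `window_len`.
#' @export
score_trial <- function(X, w, templates, window_len = ncol(templates),
                        similarity = c("inner", "pearson")) {
  similarity <- match.arg(similarity)
  s <- project_trial(X, w)
  tm <- as.matrix(templates)
  if (window_len > length(s) || window_len > ncol(tm)) {
    stop_invalid("window_len (%d) exceeds available samples", window_len)
  }
  if (similarity == "pearson" && window_len <= 1L) {
    stop_invalid("pearson similarity needs window_len > 1")
  }
  sw <- s[seq_len(window_len)]
  tw <- tm[, seq_len(window_len), drop = FALSE]
  f <- if (similarity == "inner") {
    drop(tw %*% sw)
  } else {
    # zero-variance streams (constant template or data) get score 0
    swc <- sw - mean(sw)
    twc <- tw - rowMeans(tw)
    denom <- sqrt(sum(swc^2) * rowSums(twc^2))
    ifelse(denom > 0, drop(twc %*% swc) / denom, 0)
  }
  structure(f, similarity = similarity, window_len = window_len)
}

project_trial <- function(X, w) {
  if (is.null(w)) return(as.numeric(X))
  X <- as.matrix(X)
  if (nrow(X) != length(w)) {
    stop_invalid("trial has %d channels but filter has %d", nrow(X), length(w))
  }
  drop(crossprod(as.numeric(w), X))
}

# Scores at every decision window for one trial: n_windows x n_classes matrix.
# Cumulative-sum formulation so the full stream costs one pass over samples.
score_stream <- function(X, w, templates, windows,
                         similarity = c("inner", "pearson")) {
  similarity <- match.arg(similarity)
  s <- project_trial(X, w)
  tm <- as.matrix(templates)
  windows <- as.integer(windows)
  if (max(windows) > length(s)) stop_invalid("window exceeds trial length")
  st <- tm * rep(s, each = nrow(tm)) # t_i[t] * s[t]
  cum_st <- t(apply(st, 1L, cumsum)) # n_classes x T
  if (similarity == "inner") {
    out <- t(cum_st[, windows, drop = FALSE])
  } else {
    if (any(windows <= 1L)) stop_invalid("pearson similarity needs windows > 1")
    cum_s <- cumsum(s)
    cum_s2 <- cumsum(s^2)
    cum_t <- t(apply(tm, 1L, cumsum))
    cum_t2 <- t(apply(tm^2, 1L, cumsum))
    out <- matrix(NA_real_, length(windows), nrow(tm))
    for (j in seq_along(windows)) {
      nL <- windows[j]
      cov_ <- cum_st[, nL] - cum_t[, nL] * cum_s[nL] / nL
      vt <- cum_t2[, nL] - cum_t[, nL]^2 / nL
      vs <- cum_s2[nL] - cum_s[nL]^2 / nL
      denom <- sqrt(pmax(vt * vs, 0))
      out[j, ] <- ifelse(denom > 0, cov_ / denom, 0)
    }
  }
  dimnames(out) <- NULL
  attr(out, "windows") <- windows
  attr(out, "similarity") <- similarity
  out
}

#' Classify from a score vector
#'
#' Index of the maximum similarity score; ties break toward the lowest class
#' index (deterministic).
#'
#' @param f Numeric score vector.
#' @return Integer class index (1-based).
#' @export
classify <- function(f) {
  if (length(f) == 0L) stop_invalid("empty score vector")
  which.max(f) # which.max already takes the first maximum
}

#' @rdname glance.rcca
#' @param x An `rcca` fit.
#' @param ... Unused.
#' @method tidy rcca
#' @export
tidy.rcca <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      term = paste0("w", seq_along(x$w)),
      component = "spatial_filter", estimate = x$w
    ),
    tibble::tibble(
      term = paste0("r", seq_along(x$r)),
      component = "temporal_response", estimate = x$r
    )
  )
}

#' Broom-style accessors for reconvolution CCA fits
#'
#' `tidy()` returns one row per learned coefficient (spatial filter weights
#' and temporal response samples); `glance()` returns a one-row model summary.
#'
#' @param x An `rcca` fit.
#' @param ... Unused.
#' @return A tibble.
#' @method glance rcca
#' @export
glance.rcca <- function(x, ...) {
  tibble::tibble(
    rho = x$rho,
    n_channels = length(x$w),
    kernel_len = length(x$r),
    n_classes = nrow(x$templates),
    n_samples = x$n_samples
  )
}
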