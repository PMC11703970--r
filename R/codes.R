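#' Generate one period of a linear-feedback shift register (LFSR) sequence
#'
#' Runs a Fibonacci LFSR over GF(2) defined by a feedback polynomial and
#' returns one full period of its output. When the feedback polynomial is
#' primitive the output is a maximum-length sequence (m-sequence) of period
#' `2^degree - 1`, balanced up to a single excess one (`2^(degree-1)` ones).
#'
#' @param degree Register length `d`, between 2 and 16.
#' @param taps Integer vector of tap positions in `1..degree` (exponents of the
#'   feedback polynomial; `degree` itself is always implied to be present and
#'   must be included). E.g. `c(6, 1)` for x^6 + x + 1.
#' @param init_state Binary vector of length `degree`, not all zero. Defaults
#'   to `(1, 0, ..., 0)`.
#' @param require_mseq If `TRUE` (default), error when the achieved period is
#'   shorter than `2^degree - 1` (i.e. the polynomial is not primitive);
#'   if `FALSE`, a warning is emitted instead and the shorter period returned.
#' @return A `binary_sequence`: integer vector of 0/1 with attributes
#'   `frame_rate` (NA until assigned) and `degree`.
#' @examples
#' s <- lfsr_sequence(6, c(6, 1))
#' length(s) # 63
#' sum(s)    # 32 ones: balanced
#' @export
lfsr_sequence <- function(degree, taps, init_state = NULL, require_mseq = TRUE) {
  assert_scalar_number(degree, "degree", 2, 16)
  degree <- as.integer(degree)
  taps <- sort(unique(as.integer(taps)))
  if (any(taps < 1L) || any(taps > degree) || !(degree %in% taps)) {
    stop_invalid("`taps` must lie in 1..degree and include `degree` itself")
  }
  if (is.null(init_state)) init_state <- c(1L, rep(0L, degree - 1L))
  init_state <- as.integer(init_state)
  if (length(init_state) != degree || !is_binary(init_state)) {
    stop_invalid("`init_state` must be a binary vector of length `degree`")
  }
  if (all(init_state == 0L)) stop_invalid("`init_state` must not be all zero")

  max_period <- 2L^degree - 1L
  state <- init_state
  out <- integer(max_period)
  period <- max_period
  for (k in seq_len(max_period)) {
    out[k] <- state[degree]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-degree])
    if (k < max_period && all(state == init_state)) {
      period <- k
      break
    }
  }
  if (period < max_period) {
    msg <- sprintf(
      "feedback polynomial of degree %d is not primitive: period %d < %d",
      degree, period, max_period
    )
    if (require_mseq) stop_invalid("%s", msg) else warn(msg)
    out <- out[seq_len(period)]
  }
  binary_sequence(out, frame_rate = NA_real_, degree = degree)
}

#' Construct a binary sequence object
#'
#' @param bits 0/1 vector.
#' @param frame_rate Presentation rate in Hz (frames per second).
#' @param degree Optional LFSR degree the sequence came from.
#' @return A `binary_sequence` object.
#' @export
binary_sequence <- function(bits, frame_rate = NA_real_, degree = NA_integer_) {
  bits <- as.integer(bits)
  if (!is_binary(bits)) stop_invalid("`bits` must contain only 0 and 1")
  structure(bits,
    frame_rate = frame_rate, degree = degree,
    class = c("binary_sequence", "integer")
  )
}

#' @export
print.binary_sequence <- function(x, ...) {
  cat(sprintf(
    "<binary_sequence> %d frames, %d ones, frame rate %s Hz\n",
    length(x), sum(x), format(attr(x, "frame_rate"))
  ))
  invisible(x)
}

#' Build the full Gold code family from a preferred pair of m-sequences
#'
#' Combines two same-length m-sequences `u`, `v` (from a preferred pair of
#' primitive polynomials) into the family `{u, v, u XOR shift(v, k)}` for all
#' cyclic shifts `k = 0..L-1`, giving `L + 2 = 2^d + 1` codes with bounded
#' mutual cross-correlation.
#'
#' @param seq_u,seq_v Binary sequences of equal length `L = 2^d - 1`.
#' @param frame_rate Presentation rate in Hz stamped on the resulting set.
#' @return A `code_set`: `(L + 2) x L` binary matrix with attributes
#'   `frame_rate` and `modulated = FALSE`.
#' @examples
#' u <- lfsr_sequence(5, c(5, 2))
#' v <- lfsr_sequence(5, c(5, 4, 3, 2))
#' dim(gold_code_family(u, v)) # 33 x 31
#' @export
gold_code_family <- function(seq_u, seq_v, frame_rate = NA_real_) {
  u <- as.integer(seq_u)
  v <- as.integer(seq_v)
  if (length(u) != length(v)) {
    stop_invalid(
      "preferred pair must have equal length (got %d and %d)",
      length(u), length(v)
    )
  }
  L <- length(u)
  codes <- matrix(0L, nrow = L + 2L, ncol = L)
  codes[1L, ] <- u
  codes[2L, ] <- v
  for (k in 0:(L - 1L)) {
    shifted <- v[((seq_len(L) - 1L + k) %% L) + 1L]
    codes[k + 3L, ] <- xor(u, shifted) * 1L
  }
  code_set(codes, frame_rate = frame_rate, modulated = FALSE)
}

#' Construct a stimulus code set
#'
#' @param codes Binary matrix, one row per class.
#' @param frame_rate Presentation rate in Hz.
#' @param modulated Whether the rows are two-duration modulated codes.
#' @return A `code_set` object.
#' @export
code_set <- function(codes, frame_rate = NA_real_, modulated = FALSE) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!is_binary(codes)) stop_invalid("`codes` must contain only 0 and 1")
  structure(codes,
    frame_rate = frame_rate, modulated = modulated,
    class = c("code_set", "matrix", "array")
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat(sprintf(
    "<code_set> %d codes x %d frames, frame rate %s Hz, %smodulated\n",
    nrow(x), ncol(x), format(attr(x, "frame_rate")),
    if (isTRUE(attr(x, "modulated"))) "" else "un"
  ))
  invisible(x)
}

#' Modulate codes to two flash durations
#'
#' Converts each code so that every flash (maximal run of ones) lasts exactly
#' one or two frames of the doubled-rate sequence: each frame is duplicated
#' (upsampling by 2) and the result XORed with the alternating clock
#' `0,1,0,1,...`. At a 120 Hz doubled rate this yields short flashes of
#' 1/120 s (8.33 ms) and long flashes of 2/120 s (16.67 ms), and a degree-6
#' code of 63 frames becomes `126 = 2 * (2^6 - 1)` frames.
#'
#' @param codes A `code_set` (unmodulated), or plain binary matrix.
#' @return A `code_set` at twice the frame rate with `modulated = TRUE`.
#' @export
modulate <- function(codes) {
  if (isTRUE(attr(codes, "modulated"))) {
    stop_invalid("codes are already modulated")
  }
  m <- as.matrix(codes)
  n <- ncol(m)
  up <- m[, rep(seq_len(n), each = 2L), drop = FALSE]
  clock <- rep_len(c(0L, 1L), 2L * n)
  out <- (up + matrix(clock, nrow(up), 2L * n, byrow = TRUE)) %% 2L
  fr <- attr(codes, "frame_rate")
  code_set(out,
    frame_rate = if (is.null(fr)) NA_real_ else 2 * fr,
    modulated = TRUE
  )
}

#' Select a low-correlation subset of classes by greedy search
#'
#' Greedy minimax selection on absolute pairwise Pearson correlations between
#' template responses: seed with the globally least-correlated pair, then
#' repeatedly add the candidate that minimizes the resulting maximum absolute
#' pairwise correlation. Ties break toward the lowest index.
#'
#' @param templates `n_classes x T` matrix of template responses at full trial
#'   length (a `template_set` or plain matrix).
#' @param n_subset Number of classes to keep.
#' @param exhaustive If `TRUE`, search all subsets (only allowed for at most
#'   12 available classes); used as a small-scale oracle for the greedy rule.
#' @return Sorted integer vector of selected class indices (1-based).
#' @export
select_subset <- function(templates, n_subset, exhaustive = FALSE) {
  tm <- as.matrix(templates)
  n <- nrow(tm)
  assert_scalar_number(n_subset, "n_subset", 1, Inf)
  n_subset <- as.integer(n_subset)
  if (n_subset > n) {
    stop_invalid("n_subset (%d) exceeds available classes (%d)", n_subset, n)
  }
  if (n_subset == n) return(seq_len(n))
  cm <- abs(stats::cor(t(tm)))
  diag(cm) <- 0
  if (exhaustive) {
    if (n > 12L) stop_invalid("exhaustive search allowed only for <= 12 classes")
    combos <- utils::combn(n, n_subset)
    costs <- apply(combos, 2L, function(idx) {
      if (length(idx) < 2L) return(0)
      max(cm[idx, idx])
    })
    return(sort(combos[, which.min(costs)]))
  }
  if (n_subset == 1L) return(1L)
  # seed: globally least correlated pair (lowest indices on ties)
  best <- c(1L, 2L)
  best_val <- cm[1L, 2L]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (cm[i, j] < best_val - 1e-15) {
        best <- c(i, j)
        best_val <- cm[i, j]
      }
    }
  }
  sel <- best
  while (length(sel) < n_subset) {
    candidates <- setdiff(seq_len(n), sel)
    costs <- vapply(
      candidates,
      function(k) max(cm[c(sel, k), c(sel, k)]),
      numeric(1)
    )
    sel <- c(sel, candidates[which.min(costs)])
  }
  sort(sel)
}

#' Build the event structure matrix of a stimulus code
#'
#' Extracts flash events (maximal runs of ones) from the code tiled over
#' `n_cycles` presentation cycles, classifies them as short (1 frame) or long
#' (2 frames), and lays down one shifted indicator row per (event kind, lag):
#' row `(e, m)` has a 1 in column `t` iff an event of kind `e` onsets at sample
#' `t - m`. Runs spanning a cycle border count as one event, matching
#' continuous presentation. Applying a temporal response vector to this matrix
#' reconvolves the predicted evoked response to the full sequence.
#'
#' @param code Binary vector (one modulated code; runs of ones must be of
#'   length 1 or 2 frames).
#' @param frame_rate Code presentation rate in Hz.
#' @param sample_rate EEG sampling rate in Hz; must be an integer multiple of
#'   `frame_rate`.
#' @param response_len Samples per event kind in the temporal response.
#' @param n_cycles Number of code cycles tiled into the trial.
#' @param n_samples Total columns (trial length in samples); defaults to the
#'   tiled code length in samples.
#' @return A `structure_matrix`: binary `(2 * response_len) x n_samples`
#'   matrix, event kinds ordered (short, long), with attributes
#'   `response_len`, `sample_rate`, `event_kinds`.
#' @export
structure_matrix <- function(code, frame_rate, sample_rate = frame_rate,
                             response_len, n_cycles = 1L, n_samples = NULL) {
  bits <- as.integer(code)
  if (!is_binary(bits)) stop_invalid("`code` must be binary")
  assert_scalar_number(response_len, "response_len", 1, Inf)
  response_len <- as.integer(response_len)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop_invalid("`n_cycles` must be >= 1")
  up <- sample_rate / frame_rate
  if (abs(up - round(up)) > 1e-9) {
    stop_invalid("sample_rate must be an integer multiple of frame_rate")
  }
  up <- as.integer(round(up))
  tiled <- rep(bits, n_cycles)
  if (is.null(n_samples)) n_samples <- length(tiled) * up
  n_samples <- as.integer(n_samples)

  runs <- runs_of_ones(tiled)
  if (any(runs$length > 2L)) {
    stop_invalid(
      "code has a flash of %d frames; modulated codes allow only 1- or 2-frame flashes",
      max(runs$length)
    )
  }
  kinds <- c(short = 1L, long = 2L)
  M <- matrix(0L, nrow = 2L * response_len, ncol = n_samples)
  for (e in seq_along(kinds)) {
    onsets <- (runs$start[runs$length == kinds[e]] - 1L) * up # 0-based samples
    for (m in 0:(response_len - 1L)) {
      cols <- onsets + m
      cols <- cols[cols < n_samples]
      M[(e - 1L) * response_len + m + 1L, cols + 1L] <- 1L
    }
  }
  structure(M,
    response_len = response_len, sample_rate = sample_rate,
    event_kinds = names(kinds),
    class = c("structure_matrix", "matrix", "array")
  )
}

# Structure matrices for every row of a (modulated) code set.
structure_matrices <- function(codes, sample_rate = attr(codes, "frame_rate"),
                               response_len, n_cycles = 1L, n_samples = NULL) {
  lapply(seq_len(nrow(codes)), function(i) {
    structure_matrix(codes[i, ],
      frame_rate = attr(codes, "frame_rate"),
      sample_rate = sample_rate, response_len = response_len,
      n_cycles = n_cycles, n_samples = n_samples
    )
  })
}

# A fixed, documented degree-6 preferred pair (feedback polynomials
# x^6 + x + 1 and x^6 + x^5 + x^2 + x + 1), used as the package default.
default_preferred_pair <- function() {
  list(
    u = lfsr_sequence(6, c(6, 1)),
    v = lfsr_sequence(6, c(6, 5, 2, 1))
  )
}

#' Generate the default modulated Gold code set
#'
#' Convenience wrapper: degree-6 Gold family from the package's fixed
#' preferred pair at a 60 Hz base rate, two-duration modulated to 120 Hz
#' (126-frame codes, 1.05 s cycles).
#'
#' @param frame_rate Base (pre-modulation) presentation rate in Hz.
#' @return A modulated `code_set` of 65 codes.
#' @export
default_gold_codes <- function(frame_rate = 60) {
  pair <- default_preferred_pair()
  fam <- gold_code_family(pair$u, pair$v, frame_rate = frame_rate)
  modulate(fam)
}
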