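# Zero-phase Butterworth filtering, vectorized over channels.
#
# The filter is designed with signal::butter() and applied by multiplying
# the FFT of the (reflection-padded) signal by the squared magnitude
# response |H(e^jw)|^2 -- exactly the magnitude response of a
# forward-backward (filtfilt) pass, with zero phase by construction.
# Reflection padding c(x, rev(x)) makes the periodic extension continuous
# at both ends, suppressing wrap-around transients; padding to a
# 2-3-5-smooth length keeps the FFT fast for awkward sample counts.

fft_pad_length <- function(n) stats::nextn(2L * n, c(2, 3, 5))

butter_response_sq <- function(order, edges_norm, type, nfft) {
  bt <- signal::butter(order, edges_norm, type = type)
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  ejw <- exp(-1i * outer(w, 0:(length(bt$b) - 1)))
  H <- as.vector(ejw %*% bt$b) / as.vector(ejw[, seq_along(bt$a)] %*% bt$a)
  Mod(H)^2
}

# x: numeric vector or time x channel matrix. Returns same shape.
zero_phase_filter <- function(x, fs, edges, order = 4,
                              type = c("pass", "low", "high")) {
  type <- match.arg(type)
  if (any(edges <= 0) || any(edges >= fs / 2)) {
    stop("filter band edges must lie strictly inside (0, fs/2)")
  }
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  m <- fft_pad_length(n)
  idx <- rep_len(c(seq_len(n), rev(seq_len(n))), m)
  Xp <- X[idx, , drop = FALSE]
  G <- butter_response_sq(order, edges / (fs / 2), type, m)
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * G, inverse = TRUE)) / m
  out <- Y[seq_len(n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Analytic signal of each column restricted to a band: one FFT per matrix,
# band gain applied jointly with the analytic-signal mask.
band_analytic <- function(x, fs, edges, order = 4) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  m <- fft_pad_length(n)
  idx <- rep_len(c(seq_len(n), rev(seq_len(n))), m)
  Xp <- X[idx, , drop = FALSE]
  G <- butter_response_sq(order, edges / (fs / 2), "pass", m)
  h <- numeric(m)
  h[1] <- 1
  if (m %% 2 == 0) {
    h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else h[2:((m + 1) / 2)] <- 2
  Y <- stats::mvfft(stats::mvfft(Xp) * (G * h), inverse = TRUE) / m
  out <- Y[seq_len(n), , drop = FALSE]
  if (vec) drop(out) else out
}

# Centered moving standard deviation via cumulative sums (O(n) per channel).
moving_std <- function(x, window) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(X)
  window <- max(2L, as.integer(window))
  half <- window %/% 2
  cs <- apply(rbind(0, X), 2, cumsum)
  cs2 <- apply(rbind(0, X^2), 2, cumsum)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  k <- hi - lo + 1
  s <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  s2 <- cs2[hi + 1L, , drop = FALSE] - cs2[lo, , drop = FALSE]
  v <- (s2 - s^2 / k) / pmax(k - 1, 1)
  out <- sqrt(pmax(v, 0))
  if (vec) drop(out) else out
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix (start, end).
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
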