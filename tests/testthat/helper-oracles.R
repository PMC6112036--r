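# Independent oracles and fixture builders shared across tests.

# Exhaustive DTW oracle: minimal accumulated Euclidean cost over ALL monotone
# warping paths (steps (1,0),(0,1),(1,1)), evaluated by naive recursion with
# no memoization -- every path is explored. Only usable for tiny inputs.
dtw_oracle <- function(q, r) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 1)
  if (is.null(dim(r))) r <- matrix(r, ncol = 1)
  cost <- function(i, j) sqrt(sum((q[i, ] - r[j, ])^2))
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    c0 + best
  }
  rec(nrow(q), nrow(r))
}

# random test sequence: length n, d channels
rand_seq <- function(n, d = 1) matrix(stats::rnorm(n * d), n, d)

# uniform 3-axis stream fixture
make_stream <- function(values, rate_hz = 40, ...) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  ts <- round((seq_len(nrow(values)) - 1) * 1000 / rate_hz)
  sensor_stream(ts, values, sample_rate_hz = rate_hz, ...)
}

# idle 3-axis stream (constant gravity + optional noise), n samples at 40 Hz
idle_stream <- function(n, noise_sd = 0, gravity = c(0, 0, 9.81), rate_hz = 40) {
  vals <- matrix(rep(gravity, each = n), n, 3)
  if (noise_sd > 0) vals <- vals + matrix(stats::rnorm(3 * n, 0, noise_sd), n, 3)
  make_stream(vals, rate_hz = rate_hz)
}

# plant a motif (matrix, rows = samples) into a stream at sample index i0;
# returns the modified stream
plant_motif <- function(stream, motif, i0) {
  idx <- i0:(i0 + nrow(motif) - 1)
  stream$values[idx, ] <- stream$values[idx, ] + motif
  stream
}

# a small smooth 3-axis burst: Gaussian-windowed sinusoid, n samples
burst_motif <- function(n, amp = 3, freq = 2.2, rate_hz = 40,
                        mix = c(1, 0.5, 0.2)) {
  t <- (seq_len(n) - 1) / rate_hz
  env <- exp(-(t - max(t) / 2)^2 / (2 * (max(t) / 5)^2))
  outer(env * sin(2 * pi * freq * t), mix) * amp
}
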