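# Independent brute-force oracles used across the suite. These follow the
# definitions directly (double loops, sort-and-interpolate) and never share
# code with the implementation they check.

bf_recurrence <- function(E, epsilon) {
  n <- length(E)
  Rm <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (abs(E[i] - E[j]) <= epsilon) Rm[i, j] <- 1L
  Rm
}

bf_joint <- function(Rx, Ry) {
  n <- nrow(Rx)
  J <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    J[i, j] <- Rx[i, j] * Ry[i, j]
  J
}

# RMD straight from the density definitions, given recurrence matrices
bf_rmd <- function(Rx, Ry) {
  n <- nrow(Rx)
  acc <- 0
  for (i in seq_len(n)) {
    px <- sum(Rx[i, ]) / n
    py <- sum(Ry[i, ]) / n
    pj <- sum(Rx[i, ] * Ry[i, ]) / n
    acc <- acc + pj / (px * py)
  }
  log2(acc / n)
}

# sort-and-interpolate percentile (R type-7 convention, written out)
bf_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  if (h > lo) (1 - (h - lo)) * s[lo] + (h - lo) * s[lo + 1] else s[lo]
}

bf_out_degree <- function(M) {
  n <- nrow(M)
  d <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) d[i] <- d[i] + M[i, j]
  d
}

bf_region_mean <- function(D_i, channels) {
  s <- 0
  for (ch in channels) s <- s + D_i[[ch]]
  s / length(channels)
}

# direct Riemann-sum evaluation of the Morlet transform at one (f, t0)
bf_morlet_W <- function(x, fs, f, t0_idx) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  t0 <- (t0_idx - 1) / fs
  eta <- f * (t - t0)
  psi <- pi^(-1 / 4) * exp(1i * 2 * pi * eta) * exp(-eta^2 / 2)
  sqrt(f) * sum(x * Conj(psi)) / fs
}

# tiny two-channel synthetic trial set around a single planted beta link
planted_pair_trials <- function(n_trials = 20, lag = 20, gain = 1,
                                onset_time = 0.5, snr = 50, seed = 1) {
  spec <- coupling_spec(
    data.frame(source = 1, target = 2, lag = lag, gain = gain,
               polarity = "increasing"),
    onset_time = onset_time, band = "beta")
  simulate_eeg_trials(spec, n_channels = 2, fs = 250, n_trials = n_trials,
                      snr = snr, seed = seed)
}
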