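#' Morlet continuous wavelet transform
#'
#' Complex Morlet transform of a single-channel trial,
#' `W(f, t0) = sqrt(f) * integral x(t) psi*(f (t - t0)) dt` with
#' `psi(eta) = pi^(-1/4) exp(i w0 eta) exp(-eta^2 / 2)` and central
#' frequency `w0 = 2 pi`, evaluated by discrete convolution (FFT) at each
#' grid frequency. The `sqrt(f)` prefactor is used literally; no
#' per-frequency variance rescaling is applied. Kernels are truncated at
#' `|eta| <= 5` (Gaussian tail < 4e-6); samples within one kernel
#' half-width of either trial edge fall inside the cone of influence and
#' are flagged per frequency in `coi`.
#'
#' @param x Numeric vector (one channel, one trial).
#' @param fs Sampling rate (Hz).
#' @param freqs Strictly increasing frequency grid (Hz), inside
#'   `(0, fs/2)`. Default 1-Hz steps over 4–40 Hz.
#' @return Object of class `"spectral_map"`: list with `W` (complex
#'   `length(freqs)` x `length(x)` matrix), `freqs`, `fs`, `coi`
#'   (half-width in samples per frequency), `omega0`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 2, by = 1/250))
#' m <- morlet_cwt(x, 250, freqs = 8:12)
#' which.max(abs(m$W[, 250]))   # peaks at 10 Hz
morlet_cwt <- function(x, fs, freqs = 4:40) {
  if (any(freqs <= 0) || any(freqs >= fs / 2))
    stop("frequency grid must lie inside (0, fs/2)")
  if (is.unsorted(freqs, strictly = TRUE))
    stop("frequency grid must be strictly increasing")
  n <- length(x)
  omega0 <- 2 * pi
  W <- matrix(0i, length(freqs), n)
  coi <- integer(length(freqs))
  Lmax <- ceiling(5 * fs / min(freqs))
  nfft <- 2^ceiling(log2(n + 2 * Lmax + 1))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    L <- ceiling(5 * fs / f)
    m <- (-L):L
    eta <- f * m / fs
    g <- Conj(pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2))
    h <- rev(g)                         # correlation via convolution
    H <- stats::fft(c(h, rep(0, nfft - length(h))))
    z <- stats::fft(X * H, inverse = TRUE) / nfft
    W[fi, ] <- sqrt(f) / fs * z[(L + 1):(L + n)]
    coi[fi] <- L
  }
  structure(list(W = W, freqs = freqs, fs = fs, coi = coi, omega0 = omega0),
            class = "spectral_map")
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf("Morlet spectral map: %d frequencies (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$W), x$fs))
  invisible(x)
}

band_edges <- function(band) {
  if (is.character(band))
    switch(band,
           alpha = c(8, 12),
           beta = c(15, 30),
           stop("unknown band name: ", band))
  else {
    stopifnot(length(band) == 2, band[1] < band[2])
    band
  }
}

#' Band-power envelope from a spectral map
#'
#' Integrates the wavelet amplitude `|W(f, t)|` over a frequency band by
#' the trapezoidal rule, yielding the non-negative band-power time series
#' `E(t)`. The amplitude `|W|` is integrated as such, not squared; set
#' `squared = TRUE` for an integral of `|W|^2` instead (conventional
#' spectral power).
#'
#' @param map A [morlet_cwt()] result.
#' @param band `"alpha"` (8–12 Hz), `"beta"` (15–30 Hz), or a numeric
#'   `c(lo, hi)` inside the map's grid coverage.
#' @param squared Integrate `|W|^2` instead of `|W|`.
#' @return Numeric vector `E(t)` (length = trial length, all >= 0) with
#'   attribute `band`.
#' @export
band_power <- function(map, band, squared = FALSE) {
  stopifnot(inherits(map, "spectral_map"))
  edges <- band_edges(band)
  if (edges[1] < min(map$freqs) || edges[2] > max(map$freqs))
    stop("band lies outside the frequency grid coverage")
  sel <- which(map$freqs >= edges[1] & map$freqs <= edges[2])
  if (length(sel) < 2) stop("band covers fewer than two grid frequencies")
  A <- abs(map$W[sel, , drop = FALSE])
  if (squared) A <- A^2
  f <- map$freqs[sel]
  w <- diff(f)
  # trapezoid weights over the band's grid
  tw <- c(w[1] / 2, (w[-1] + w[-length(w)]) / 2, w[length(w)] / 2)
  if (length(f) == 2) tw <- c(w / 2, w / 2)
  E <- as.numeric(crossprod(A, tw))
  attr(E, "band") <- if (is.character(band)) band else paste(edges, collapse = "-")
  E
}

#' Band-power envelopes for a whole trial set
#'
#' Runs the Morlet transform and band integration for every channel and
#' trial, then low-pass filters (zero-phase Butterworth, order 4, `lp_cutoff`
#' Hz) and decimates the envelopes by `decimate` — the recurrence analysis
#' operates on slow envelope dynamics, and decimation keeps its cost
#' proportionate. With the defaults (250 Hz in, decimate 10) envelopes come
#' out at 25 Hz.
#'
#' @param trials An `"eeg_trials"` object.
#' @param band `"alpha"` or `"beta"` (or numeric edges).
#' @param freqs Frequency grid for the transform; defaults to 1-Hz steps
#'   spanning just the requested band.
#' @param decimate Integer decimation factor (1 = none).
#' @param lp_cutoff Anti-alias low-pass cutoff (Hz) applied before
#'   decimation.
#' @param squared Passed to [band_power()].
#' @return Object of class `"band_power_set"`: list with `env`
#'   (samples x channels x trials at the decimated rate), `band`, `fs`
#'   (envelope rate), `onset_index` (0-based onset sample at that rate),
#'   `channel_labels`, `meta`.
#' @export
extract_band_envelopes <- function(trials, band, freqs = NULL, decimate = 10,
                                   lp_cutoff = 8, squared = FALSE) {
  stopifnot(inherits(trials, "eeg_trials"))
  edges <- band_edges(band)
  if (is.null(freqs)) freqs <- seq(edges[1], edges[2], by = 1)
  d <- dim(trials$data)
  fs <- trials$fs
  if (trials$onset_index %% decimate != 0)
    stop("onset index must be divisible by the decimation factor")
  n_out <- d[2] %/% decimate
  env <- array(0, dim = c(n_out, d[1], d[3]))
  bf <- if (decimate > 1) signal::butter(4, lp_cutoff / (fs / 2), type = "low")
        else NULL
  for (tr in seq_len(d[3])) {
    for (ch in seq_len(d[1])) {
      E <- band_power(morlet_cwt(trials$data[ch, , tr], fs, freqs), edges,
                      squared = squared)
      if (decimate > 1) {
        E <- signal::filtfilt(bf, E)
        E <- pmax(E, 0)                 # filtering can undershoot slightly
        E <- E[seq(1, d[2], by = decimate)]
      }
      env[, ch, tr] <- E
    }
  }
  structure(list(env = env, band = if (is.character(band)) band
                   else paste(edges, collapse = "-"),
                 fs = fs / decimate,
                 onset_index = trials$onset_index %/% decimate,
                 channel_labels = trials$channel_labels,
                 meta = trials$meta),
            class = "band_power_set")
}

#' @export
print.band_power_set <- function(x, ...) {
  d <- dim(x$env)
  cat(sprintf("%s-band power envelopes: %d samples x %d channels x %d trials @ %g Hz\n",
              x$band, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Neighboring-electrode correlation QC
#'
#' Field-spread screening: Pearson correlation of band-power envelopes for
#' every montage-adjacent channel pair over the pre-stimulus baseline
#' segment (concatenated across trials), summarized by the median. The set
#' passes when the median is strictly below `threshold` (default 0.6) —
#' high neighbor correlations would indicate that volume conduction, not
#' neural coupling, dominates the envelopes.
#'
#' @param bp A `band_power_set`.
#' @param adjacency Two-column matrix of neighboring channel-label pairs
#'   (default [montage_adjacency()] on the set's labels).
#' @param threshold Pass threshold (strict inequality).
#' @return List: `median` (median neighbor correlation), `pass`
#'   (`median < threshold`), `per_pair` (named vector), `band`.
#' @export
neighbor_correlation_qc <- function(bp, adjacency = NULL, threshold = 0.6) {
  stopifnot(inherits(bp, "band_power_set"))
  if (is.null(adjacency)) adjacency <- montage_adjacency(bp$channel_labels)
  if (!nrow(adjacency)) stop("no adjacent channel pairs")
  base_idx <- seq_len(bp$onset_index)
  rho <- apply(adjacency, 1, function(pr) {
    i <- resolve_channels(pr[1], bp$channel_labels)
    j <- resolve_channels(pr[2], bp$channel_labels)
    cor(as.vector(bp$env[base_idx, i, ]), as.vector(bp$env[base_idx, j, ]))
  })
  names(rho) <- paste(adjacency[, 1], adjacency[, 2], sep = "-")
  med <- median(rho)
  list(median = med, pass = med < threshold, per_pair = rho, band = bp$band)
}
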