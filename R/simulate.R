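#' Behavioral model for an ambiguous-stimulus session
#'
#' Parameters of the simulated behavioral experiment: a session of Necker
#' cube presentations with ambiguity `g` drawn from a fixed stimulus set,
#' log-normally distributed reaction times whose median depends on the
#' ambiguity class, and an optional training drift that makes
#' high-complexity reaction times shrink over the session.
#'
#' Defaults follow the study conditions: stimulus set
#' `g in {0, 0.15, 0.4, 0.45, 0.55, 0.6, 0.85, 1}` split into a
#' high-ambiguity (HC) subset `{0.4, 0.45, 0.55, 0.6}` and a low-ambiguity
#' (LC) subset; median RT 1.1 s (HC) and 0.8 s (LC); presentation duration
#' uniform on \[1, 1.5\] s in 0.016-s steps; inter-stimulus interval uniform
#' on \[3, 5\] s in 0.064-s steps.
#'
#' @param g_set Ambiguity values presented.
#' @param g_high Subset of `g_set` forming the high-complexity class.
#' @param median_rt_hc,median_rt_lc Median reaction times (s) for the
#'   high/low complexity classes. Must satisfy `median_rt_hc > median_rt_lc > 0`.
#' @param dispersion Log-normal `sdlog` of the RT distribution (0 gives
#'   degenerate RTs exactly at the class median).
#' @param training_drift Fractional decrease of the HC median RT across the
#'   session: the instantaneous HC median is
#'   `median_rt_hc * (1 + training_drift * (0.5 - u))` at session fraction
#'   `u`, so it falls linearly while its session average stays at
#'   `median_rt_hc`. Default 0.55 reproduces the reported ~1.4 s (start) vs
#'   ~0.8 s (end) HC medians.
#' @param presentation_range,presentation_step Presentation duration range (s)
#'   and quantization step.
#' @param isi_range,isi_step Inter-stimulus interval range (s) and step.
#' @return Object of class `"behavioral_model"`.
#' @export
behavioral_model <- function(g_set = c(0, 0.15, 0.4, 0.45, 0.55, 0.6, 0.85, 1),
                             g_high = c(0.4, 0.45, 0.55, 0.6),
                             median_rt_hc = 1.1,
                             median_rt_lc = 0.8,
                             dispersion = 0.3,
                             training_drift = 0.55,
                             presentation_range = c(1, 1.5),
                             presentation_step = 0.016,
                             isi_range = c(3, 5),
                             isi_step = 0.064) {
  if (!(median_rt_hc > median_rt_lc && median_rt_lc > 0))
    stop("invalid behavioral model: need median_rt_hc > median_rt_lc > 0")
  if (dispersion < 0) stop("invalid behavioral model: dispersion must be >= 0")
  if (!all(g_high %in% g_set)) stop("g_high must be a subset of g_set")
  if (any(g_set < 0 | g_set > 1)) stop("g values must lie in [0, 1]")
  structure(list(
    g_set = g_set, g_high = g_high, g_low = setdiff(g_set, g_high),
    median_rt_hc = median_rt_hc, median_rt_lc = median_rt_lc,
    dispersion = dispersion, training_drift = training_drift,
    presentation_range = presentation_range, presentation_step = presentation_step,
    isi_range = isi_range, isi_step = isi_step
  ), class = "behavioral_model")
}

#' @export
print.behavioral_model <- function(x, ...) {
  cat("Behavioral model: ", length(x$g_set), " ambiguity levels (",
      length(x$g_high), " HC)\n", sep = "")
  cat(sprintf("  median RT: HC %.3g s, LC %.3g s; dispersion sdlog %.3g; drift %.3g\n",
              x$median_rt_hc, x$median_rt_lc, x$dispersion, x$training_drift))
  invisible(x)
}

quantized_runif <- function(n, range, step) {
  k <- floor((range[2] - range[1]) / step)
  range[1] + step * sample.int(k + 1L, n, replace = TRUE) - step
}

#' Simulate a behavioral table of reaction times
#'
#' Draws one session of trials: ambiguity uniformly from the stimulus set,
#' presentation onsets accumulated from quantized presentation durations and
#' inter-stimulus intervals, and reaction times from a log-normal whose
#' median is the ambiguity class median, modulated for HC trials by the
#' training-drift factor at the trial's position in the session.
#'
#' @param model A [behavioral_model()].
#' @param n_trials Number of trials (> 0).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A `data.frame` of class `"behavioral_table"` with columns
#'   `trial_id`, `g`, `complexity` ("HC"/"LC"), `onset_s` (session time of
#'   stimulus onset), `presentation_s`, `rt_s`, `response`.
#' @export
#' @examples
#' b <- simulate_rts(behavioral_model(training_drift = 0), 200, seed = 1)
#' median(b$rt_s[b$complexity == "HC"])
simulate_rts <- function(model, n_trials, seed = NULL) {
  stopifnot(inherits(model, "behavioral_model"))
  if (n_trials <= 0) stop("n_trials must be positive")
  local_seed(seed, {
    g <- sample(model$g_set, n_trials, replace = TRUE)
    hc <- g %in% model$g_high
    pres <- quantized_runif(n_trials, model$presentation_range, model$presentation_step)
    isi <- quantized_runif(n_trials, model$isi_range, model$isi_step)
    onset <- cumsum(isi) + c(0, cumsum(pres))[seq_len(n_trials)]
    u <- if (n_trials > 1) (onset - onset[1]) / (onset[n_trials] - onset[1]) else 0.5
    med <- ifelse(hc,
                  model$median_rt_hc * (1 + model$training_drift * (0.5 - u)),
                  model$median_rt_lc)
    rt <- rlnorm(n_trials, meanlog = log(med), sdlog = model$dispersion)
    out <- data.frame(
      trial_id = seq_len(n_trials),
      g = g,
      complexity = ifelse(hc, "HC", "LC"),
      onset_s = onset,
      presentation_s = pres,
      rt_s = rt,
      response = sample(c("left", "right"), n_trials, replace = TRUE),
      stringsAsFactors = FALSE
    )
    class(out) <- c("behavioral_table", "data.frame")
    out
  })
}

#' Coupling specification for the EEG simulator
#'
#' Describes the directed lagged envelope couplings planted in synthetic
#' trials: a set of links (source channel, target channel, lag in samples,
#' gain, polarity), the post-stimulus time `onset_time` at which the
#' coupling regime switches, and the frequency band it acts in.
#'
#' Polarity "increasing" means the target's band envelope becomes a
#' gain-weighted lagged copy of the source's envelope *after* `onset_time`;
#' "decreasing" means source and target share a common envelope component
#' *before* `onset_time` only (baseline coupling that the stimulus removes).
#'
#' @param links `data.frame` with columns `source`, `target` (channel
#'   indices, 1-based), `lag` (samples, >= 1: zero-lag coupling is never
#'   planted, mirroring the analysis' exclusion of instantaneous
#'   dependence), `gain` (in \[0, 1\]) and `polarity`
#'   ("increasing"/"decreasing").
#' @param onset_time Seconds post-stimulus at which the coupling switches
#'   (in `[0, 3)`).
#' @param band `"alpha"` or `"beta"`.
#' @return Object of class `"coupling_spec"`.
#' @export
coupling_spec <- function(links, onset_time = 0.5, band = c("beta", "alpha")) {
  band <- match.arg(band)
  links <- as.data.frame(links)
  need <- c("source", "target", "lag", "gain", "polarity")
  if (!all(need %in% names(links)))
    stop("links must have columns: ", paste(need, collapse = ", "))
  if (any(links$source == links$target))
    stop("self-coupling (source == target) is not allowed")
  if (any(links$lag < 1)) stop("all lags must be >= 1 sample")
  if (any(links$gain < 0 | links$gain > 1)) stop("gains must lie in [0, 1]")
  if (!all(links$polarity %in% c("increasing", "decreasing")))
    stop("polarity must be 'increasing' or 'decreasing'")
  if (onset_time < 0 || onset_time >= 3)
    stop("onset_time must lie in [0, 3) seconds post-stimulus")
  structure(list(links = links, onset_time = onset_time, band = band),
            class = "coupling_spec")
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("Coupling spec: %d %s-band link(s), switching at %.3g s post-stimulus\n",
              nrow(x$links), x$band, x$onset_time))
  print(x$links, row.names = FALSE)
  invisible(x)
}

#' Slow non-negative envelope process
#'
#' The simulator's envelope primitive: a rectified, low-pass-filtered
#' Gaussian process. White noise is zero-phase low-pass filtered (Butterworth,
#' order 4) at `cutoff` Hz, scaled to unit standard deviation, and rectified,
#' giving a non-negative series whose fluctuations live below `cutoff`.
#'
#' @param n Length in samples.
#' @param fs Sampling rate (Hz).
#' @param cutoff Envelope bandwidth (Hz), default 4 — slow enough to be
#'   resolvable inside 1-s analysis windows.
#' @param seed Optional seed.
#' @return Numeric vector of length `n`, all values >= 0.
#' @export
simulate_envelope <- function(n, fs, cutoff = 4, seed = NULL) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  local_seed(seed, {
    pad <- ceiling(2 * fs / cutoff)
    w <- rnorm(n + 2 * pad)
    bf <- signal::butter(4, cutoff / (fs / 2), type = "low")
    e <- signal::filtfilt(bf, w)[(pad + 1):(pad + n)]
    abs(e / stats::sd(e))
  })
}

#' Pair of envelopes with a planted lagged coupling
#'
#' Generates a source envelope and a target envelope equal to a gain-weighted
#' copy of the source delayed by `lag` samples, plus an independent envelope
#' residual whose scale is set by `snr` relative to the full source
#' envelope (an absolute noise floor, so lowering the gain weakens the
#' planted dependence). With `snr = Inf` the target is exactly the lagged,
#' scaled source.
#'
#' @param n Length in samples.
#' @param lag Delay in samples (>= 1).
#' @param gain Coupling gain in \[0, 1\].
#' @param snr Source-envelope variance / residual variance (`Inf` = no
#'   residual).
#' @param fs,cutoff Passed to [simulate_envelope()].
#' @param seed Optional seed.
#' @return List with elements `x` (source), `y` (target), `lag`.
#' @export
simulate_coupled_envelopes <- function(n, lag, gain = 1, snr = Inf,
                                       fs = 25, cutoff = 4, seed = NULL) {
  if (lag < 1) stop("lag must be >= 1 sample")
  local_seed(seed, {
    full <- simulate_envelope(n + lag, fs, cutoff)
    x <- full[(lag + 1):(lag + n)]
    y <- gain * full[1:n]
    if (is.finite(snr)) {
      resid <- simulate_envelope(n, fs, cutoff)
      y <- y + resid * stats::sd(full[1:n]) / (sqrt(snr) * stats::sd(resid))
    }
    list(x = x, y = y, lag = lag)
  })
}

# 1/f ("pink") background noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  nf <- 2^ceiling(log2(n))
  spec <- stats::fft(rnorm(nf))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)          # symmetric bin distance from DC
  spec <- spec / sqrt(f)
  spec[1] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n]
  x / stats::sd(x)
}

# Fraction of pink-noise variance falling inside [f1, f2] Hz for the shaping
# used above (power ~ 1/f over (0, fs/2]); analytic, used for SNR scaling.
pink_band_fraction <- function(fs, f1, f2, fmin = 0.5) {
  log(f2 / f1) / log((fs / 2) / fmin)
}

#' Simulate event-locked multichannel EEG-like trials
#'
#' Each trial is 4 s long (1 s pre-stimulus baseline + 3 s post-stimulus):
#' per channel, an alpha-band (10 Hz) and a beta-band (22.5 Hz) carrier,
#' each amplitude-modulated by a slow non-negative envelope
#' ([simulate_envelope()]), plus 1/f background noise. Couplings from
#' `spec` act on the envelopes of the spec's band: increasing links make
#' the target envelope a gain-weighted lagged copy of the source envelope
#' after the coupling onset; decreasing links give source and target a
#' shared envelope component during the baseline only.
#'
#' `snr` is the ratio of band-carrier variance to in-band (8–30 Hz) noise
#' variance; `snr = Inf` disables noise. Output is unitless with carriers
#' of amplitude ~1 (nominally interpretable as tens of microvolts).
#'
#' @param spec A [coupling_spec()] (may have zero links).
#' @param model Optional [behavioral_model()]; when given, per-trial
#'   metadata (g, RT, session onset) is drawn via [simulate_rts()].
#' @param n_channels Number of channels (>= 2; default 31 uses the
#'   default 10-10 montage labels).
#' @param fs Sampling rate (Hz), must exceed twice the upper beta edge.
#' @param n_trials Number of trials.
#' @param snr Carrier-to-noise variance ratio, in band.
#' @param seed Optional seed; identical inputs + seed give bit-identical output.
#' @return Object of class `"eeg_trials"`: list with `data`
#'   (channels x samples x trials), `fs`, `channel_labels`, `onset_index`
#'   (0-based sample of stimulus onset; equals `fs`, i.e. 1 s of baseline),
#'   `meta` (per-trial data.frame) and `envelopes` (list of
#'   samples x channels x trials arrays, per band — the generator's ground
#'   truth).
#' @export
#' @examples
#' spec <- coupling_spec(data.frame(source = 1, target = 2, lag = 5,
#'                                  gain = 1, polarity = "increasing"),
#'                       onset_time = 0.5, band = "beta")
#' tr <- simulate_eeg_trials(spec, n_channels = 4, n_trials = 2, seed = 1)
#' dim(tr$data)
simulate_eeg_trials <- function(spec, model = NULL, n_channels = 31, fs = 250,
                                n_trials = 10, snr = 50, seed = NULL) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (n_channels < 2) stop("need at least 2 channels")
  if (fs <= 2 * 30) stop("fs must exceed twice the upper beta edge (30 Hz)")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (nrow(spec$links) &&
      any(c(spec$links$source, spec$links$target) > n_channels |
          c(spec$links$source, spec$links$target) < 1))
    stop("coupling spec references channels outside 1..n_channels")

  n_samp <- 4L * fs
  onset_index <- 1L * fs                    # 0-based onset sample
  switch_idx <- onset_index + round(spec$onset_time * fs) + 1L  # first 1-based sample of new regime
  carrier_freq <- c(alpha = 10, beta = 22.5)
  tgrid <- (seq_len(n_samp) - 1) / fs

  local_seed(seed, {
    meta <- if (!is.null(model)) {
      simulate_rts(model, n_trials)
    } else {
      data.frame(trial_id = seq_len(n_trials), g = NA_real_,
                 complexity = NA_character_, onset_s = NA_real_,
                 presentation_s = NA_real_, rt_s = NA_real_,
                 response = NA_character_, stringsAsFactors = FALSE)
    }
    data <- array(0, dim = c(n_channels, n_samp, n_trials))
    envs <- list(alpha = array(0, dim = c(n_samp, n_channels, n_trials)),
                 beta  = array(0, dim = c(n_samp, n_channels, n_trials)))

    for (tr in seq_len(n_trials)) {
      for (band in c("alpha", "beta")) {
        E <- matrix(0, n_samp, n_channels)
        for (ch in seq_len(n_channels))
          E[, ch] <- simulate_envelope(n_samp, fs)
        if (band == spec$band && nrow(spec$links)) {
          base <- E
          dec <- spec$links[spec$links$polarity == "decreasing", , drop = FALSE]
          for (l in seq_len(nrow(dec))) {
            # lagged shared component: the zero-lag exclusion in the RMD
            # scan would blind the analysis to an unlagged common envelope
            common <- simulate_envelope(n_samp + dec$lag[l], fs)
            pre <- seq_len(min(switch_idx - 1L, n_samp))
            g <- dec$gain[l]
            E[pre, dec$source[l]] <- sqrt(1 - g^2) * base[pre, dec$source[l]] +
              g * common[pre + dec$lag[l]]
            E[pre, dec$target[l]] <- sqrt(1 - g^2) * base[pre, dec$target[l]] +
              g * common[pre]
          }
          inc <- spec$links[spec$links$polarity == "increasing", , drop = FALSE]
          if (nrow(inc)) {
            post <- switch_idx:n_samp
            for (tgt in unique(inc$target)) {
              li <- inc[inc$target == tgt, , drop = FALSE]
              coupled <- rep(0, length(post))
              for (l in seq_len(nrow(li)))
                coupled <- coupled +
                  li$gain[l] * base[post - li$lag[l], li$source[l]]
              coupled <- coupled / nrow(li)
              if (is.finite(snr)) {
                resid <- simulate_envelope(n_samp, fs)[post]
                coupled <- coupled +
                  resid * stats::sd(coupled) / (sqrt(snr) * stats::sd(resid))
              }
              E[post, tgt] <- coupled
            }
          }
        }
        envs[[band]][, , tr] <- E
        phase <- runif(n_channels, 0, 2 * pi)
        for (ch in seq_len(n_channels))
          data[ch, , tr] <- data[ch, , tr] +
            E[, ch] * cos(2 * pi * carrier_freq[band] * tgrid + phase[ch])
      }
      if (is.finite(snr)) {
        rho <- pink_band_fraction(fs, 8, 30)
        for (ch in seq_len(n_channels)) {
          carrier_var <- stats::var(data[ch, , tr])
          data[ch, , tr] <- data[ch, , tr] +
            pink_noise(n_samp) * sqrt(carrier_var / (snr * rho))
        }
      }
    }
    labels <- if (n_channels == 31) default_montage()
              else sprintf("Ch%02d", seq_len(n_channels))
    structure(list(data = data, fs = fs, channel_labels = labels,
                   onset_index = onset_index, meta = meta, envelopes = envs,
                   spec = spec),
              class = "eeg_trials")
  })
}

#' @export
print.eeg_trials <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EEG trial set: %d channels x %d samples x %d trials @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  stimulus onset at sample %d (%.3g s baseline)\n",
              x$onset_index, x$onset_index / x$fs))
  invisible(x)
}

#' Frontal-hub coupling preset
#'
#' A coupling specification in which every increasing-link source lies in
#' the frontal (F) or prefrontal (Fp) region and targets are spread
#' round-robin over the remaining regions: the beta-band frontal-driver
#' topology used for end-to-end recovery experiments. Each frontal channel
#' sources `targets_per_source` increasing links (default 2), so the preset
#' contains `2 * |F union Fp|` hub links (16 for the default montage).
#'
#' In addition, `n_decreasing` decreasing links (default 4) are planted
#' between posterior channel pairs: baseline-only envelope couplings that
#' the stimulus removes. They keep the decreasing-link network non-empty so
#' the link ratio R(t) stays finite and the network-formation timeline is
#' well defined, mirroring the coexistence of increasing and decreasing
#' links in recorded data.
#'
#' @param n_channels Channel count; labels taken from [default_montage()]
#'   when 31.
#' @param region_map Region parcellation; must contain regions `F` and `Fp`.
#' @param onset_time Post-stimulus switch time of the couplings (s).
#' @param gain Coupling gain for every link.
#' @param lag Coupling lag in samples (at the simulator's sampling rate).
#' @param targets_per_source Increasing links per frontal source channel.
#' @param n_decreasing Number of posterior baseline (decreasing) links.
#' @return A [coupling_spec()] with `band = "beta"`.
#' @export
preset_frontal_hub_spec <- function(n_channels = 31,
                                    region_map = default_region_map(),
                                    onset_time = 0.6, gain = 1, lag = 20,
                                    targets_per_source = 2,
                                    n_decreasing = 4) {
  if (!all(c("F", "Fp") %in% names(region_map)))
    stop("region map must contain regions 'F' and 'Fp'")
  labels <- if (n_channels == 31) default_montage()
            else sprintf("Ch%02d", seq_len(n_channels))
  validate_region_map(region_map, labels)
  frontal <- c(region_map[["F"]], region_map[["Fp"]])
  src_idx <- match(frontal, labels)
  tgt_pool <- setdiff(seq_len(n_channels), src_idx)
  n_links <- length(src_idx) * targets_per_source
  if (n_links > length(tgt_pool))
    stop("not enough non-frontal channels for distinct targets")
  targets <- tgt_pool[seq_len(n_links)]
  links <- data.frame(
    source = rep(src_idx, each = targets_per_source),
    target = targets,
    lag = lag, gain = gain, polarity = "increasing",
    stringsAsFactors = FALSE
  )
  if (n_decreasing > 0) {
    # posterior baseline couplings: pair up the most occipital channels
    post_idx <- setdiff(seq_len(min(2 * n_decreasing, n_channels)), src_idx)
    if (length(post_idx) < 2 * n_decreasing)
      stop("not enough posterior channels for the decreasing links")
    dec <- data.frame(
      source = post_idx[seq_len(n_decreasing) * 2 - 1],
      target = post_idx[seq_len(n_decreasing) * 2],
      lag = lag, gain = gain, polarity = "decreasing",
      stringsAsFactors = FALSE
    )
    links <- rbind(links, dec)
  }
  coupling_spec(links, onset_time = onset_time, band = "beta")
}
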