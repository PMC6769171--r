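#' Zero-phase band-pass and notch filtering
#'
#' Applies the standard EEG preprocessing chain to a continuous recording:
#' a Butterworth high-pass (order 2) at `hp`, low-pass (order 4) at `lp`,
#' and a band-stop notch (order 2, +/- 2 Hz) at `notch`, each applied
#' forward-backward (`signal::filtfilt`) so the chain is zero-phase —
#' filter delay therefore cannot bias event-locked timing estimates
#' downstream. Defaults: 1–100 Hz band-pass with a 50-Hz notch.
#'
#' @param x Numeric vector or channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param hp,lp High-/low-pass cutoffs (Hz), `hp < lp < fs/2`.
#' @param notch Notch center (Hz), or `NULL` to skip.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_notch_filter <- function(x, fs, hp = 1, lp = 100, notch = 50) {
  if (!(hp < lp)) stop("need hp < lp")
  if (lp >= fs / 2) stop("sampling rate too low for the requested low-pass cutoff")
  if (!is.null(notch) && notch + 2 >= fs / 2)
    stop("sampling rate too low for the requested notch")
  filts <- list(signal::butter(2, hp / (fs / 2), type = "high"),
                signal::butter(4, lp / (fs / 2), type = "low"))
  if (!is.null(notch))
    filts <- c(filts, list(signal::butter(2, c(notch - 2, notch + 2) / (fs / 2),
                                          type = "stop")))
  apply_filt <- function(v) {
    for (bf in filts) v <- signal::filtfilt(bf, v)
    v
  }
  if (is.matrix(x)) t(apply(x, 1, apply_filt)) else apply_filt(x)
}

#' Segment a continuous recording into event-locked trials
#'
#' Cuts 4-s trials around each stimulus onset: 1 s before and 3 s after.
#' Onsets come from the events table, either as `onset_sample` (0-based
#' sample index) or `onset_s` (seconds). Onsets too close to a record edge
#' are dropped with a warning; remaining trials keep their event metadata,
#' ordered by onset.
#'
#' @param continuous Channels x samples matrix.
#' @param fs Sampling rate (Hz).
#' @param events Data frame with `onset_sample` or `onset_s` plus any
#'   per-trial metadata (g, rt_s, ...), e.g. a [simulate_rts()] table.
#' @param channel_labels Optional labels (default `Ch01`, ... or rownames).
#' @return An `"eeg_trials"` object (see [simulate_eeg_trials()]).
#' @export
segment_trials <- function(continuous, fs, events, channel_labels = NULL) {
  stopifnot(is.matrix(continuous))
  n_samp_rec <- ncol(continuous)
  onset <- if ("onset_sample" %in% names(events)) as.integer(events$onset_sample)
           else if ("onset_s" %in% names(events)) as.integer(round(events$onset_s * fs))
           else stop("events must contain onset_sample or onset_s")
  ord <- order(onset)
  events <- events[ord, , drop = FALSE]
  onset <- onset[ord]
  pre <- 1L * fs
  post <- 3L * fs
  ok <- onset - pre >= 0 & onset + post <= n_samp_rec
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) dropped: onset too close to record edge")
    events <- events[ok, , drop = FALSE]
    onset <- onset[ok]
  }
  n_tr <- length(onset)
  if (n_tr == 0) stop("no trials can be segmented from this recording")
  data <- array(0, dim = c(nrow(continuous), pre + post, n_tr))
  for (k in seq_len(n_tr))
    data[, , k] <- continuous[, (onset[k] - pre + 1):(onset[k] + post)]
  labels <- channel_labels %||% rownames(continuous) %||%
    sprintf("Ch%02d", seq_len(nrow(continuous)))
  structure(list(data = data, fs = fs, channel_labels = labels,
                 onset_index = pre, meta = as.data.frame(events),
                 envelopes = NULL, spec = NULL),
            class = "eeg_trials")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reject high-amplitude trials
#'
#' Removes trials whose peak absolute amplitude exceeds `amp_threshold` on
#' any channel — a simple stand-in for artifact screening. The removal log
#' (trial id and peak amplitude) is kept in the `"rejected"` attribute.
#'
#' @param trials An `"eeg_trials"` object.
#' @param amp_threshold Positive amplitude threshold (signal units).
#' @return The trial set with offending trials removed.
#' @export
reject_artifact_trials <- function(trials, amp_threshold) {
  stopifnot(inherits(trials, "eeg_trials"))
  if (amp_threshold <= 0) stop("amp_threshold must be positive")
  peaks <- apply(abs(trials$data), 3, max)
  bad <- peaks > amp_threshold
  if (all(bad)) stop("all trials exceed the amplitude threshold: empty trial set")
  out <- trials
  out$data <- trials$data[, , !bad, drop = FALSE]
  out$meta <- trials$meta[!bad, , drop = FALSE]
  if (!is.null(trials$envelopes))
    out$envelopes <- lapply(trials$envelopes, function(a) a[, , !bad, drop = FALSE])
  attr(out, "rejected") <- data.frame(
    trial_id = trials$meta$trial_id[bad],
    peak = peaks[bad])
  out
}

#' Assign SH1 / SH2 / SE2 condition labels from reaction times
#'
#' Trials are split by stimulus ambiguity into high-complexity (HC,
#' `g` in `high_g_set`) and low-complexity (LC) classes, then assigned:
#' \describe{
#'   \item{SH1}{HC trials with RT in the \[75th, 97.5th\] percentile interval
#'     of the HC RT distribution (long-RT hard trials).}
#'   \item{SH2}{HC trials with RT between the LC and HC medians (short-RT
#'     hard trials).}
#'   \item{SE2}{LC trials with RT in the same inter-median interval
#'     (easy trials matched to SH2 RTs).}
#' }
#' Percentiles use R's default linear interpolation (type 7); interval
#' endpoints are inclusive on both sides so boundary trials are never
#' silently dropped. Exactly `K` trials per condition are then retained by
#' seeded uniform subsampling.
#'
#' @param behavior A behavioral table with columns `trial_id`, `g`, `rt_s`.
#' @param high_g_set,low_g_set Ambiguity values of the HC / LC classes
#'   (defaults match [behavioral_model()]).
#' @param K Trials retained per condition (default 20).
#' @param seed Seed for the subsampling.
#' @return Object of class `"condition_assignment"`: data.frame
#'   (`trial_id`, `label`) covering all trials (`"unassigned"` elsewhere),
#'   with attributes `K`, `bounds` (the percentile/median interval edges)
#'   and `eligible` (pre-subsampling trial ids per condition).
#' @export
assign_conditions <- function(behavior,
                              high_g_set = c(0.4, 0.45, 0.55, 0.6),
                              low_g_set = c(0, 0.15, 0.85, 1),
                              K = 20, seed = NULL) {
  stopifnot(all(c("trial_id", "g", "rt_s") %in% names(behavior)))
  hc <- behavior$g %in% high_g_set
  lc <- behavior$g %in% low_g_set
  if (!any(hc) || !any(lc)) stop("both ambiguity classes must be non-empty")
  rt_hc <- behavior$rt_s[hc]
  rt_lc <- behavior$rt_s[lc]
  p <- quantile(rt_hc, c(0.75, 0.975), type = 7, names = FALSE)
  m_lc <- median(rt_lc)
  m_hc <- median(rt_hc)
  elig <- list(
    SH1 = behavior$trial_id[hc & behavior$rt_s >= p[1] & behavior$rt_s <= p[2]],
    SH2 = behavior$trial_id[hc & behavior$rt_s >= m_lc & behavior$rt_s <= m_hc],
    SE2 = behavior$trial_id[lc & behavior$rt_s >= m_lc & behavior$rt_s <= m_hc]
  )
  short <- names(elig)[vapply(elig, length, 1L) < K]
  if (length(short))
    stop("fewer than K = ", K, " eligible trials for condition(s): ",
         paste(short, collapse = ", "))
  local_seed(seed, {
    chosen <- lapply(elig, function(ids) sort(sample(ids, K)))
    label <- rep("unassigned", nrow(behavior))
    for (cond in names(chosen))
      label[behavior$trial_id %in% chosen[[cond]]] <- cond
    out <- data.frame(trial_id = behavior$trial_id, label = label,
                      stringsAsFactors = FALSE)
    structure(out, class = c("condition_assignment", "data.frame"),
              K = K, eligible = elig,
              bounds = c(sh1_lo = p[1], sh1_hi = p[2],
                         med_lc = m_lc, med_hc = m_hc))
  })
}

#' Reaction-time summary by complexity class and condition
#'
#' Medians per ambiguity class (HC/LC), their difference, a two-sided
#' rank-sum test between the classes, and (when an assignment is given)
#' per-condition medians.
#'
#' @param behavior Behavioral table with `g`, `rt_s` and `complexity`
#'   (or `g` resolvable via the default ambiguity split).
#' @param assignment Optional [assign_conditions()] result.
#' @return List of class `"rt_summary"`: `class_medians`, `difference`
#'   (HC - LC, s), `rank_test` (htest), `condition_medians` (or NULL).
#' @export
summarize_rts <- function(behavior, assignment = NULL) {
  if (!"complexity" %in% names(behavior))
    behavior$complexity <- ifelse(behavior$g %in% c(0.4, 0.45, 0.55, 0.6),
                                  "HC", "LC")
  rt_hc <- behavior$rt_s[behavior$complexity == "HC"]
  rt_lc <- behavior$rt_s[behavior$complexity == "LC"]
  if (!length(rt_hc) || !length(rt_lc)) stop("empty complexity class")
  cm <- c(HC = median(rt_hc), LC = median(rt_lc))
  rk <- suppressWarnings(wilcox.test(rt_hc, rt_lc, alternative = "two.sided"))
  cond <- NULL
  if (!is.null(assignment)) {
    merged <- merge(behavior, as.data.frame(assignment), by = "trial_id")
    keep <- merged$label != "unassigned"
    cond <- tapply(merged$rt_s[keep], merged$label[keep], median)
  }
  structure(list(class_medians = cm, difference = unname(cm["HC"] - cm["LC"]),
                 rank_test = rk, condition_medians = cond),
            class = "rt_summary")
}

#' @export
print.rt_summary <- function(x, ...) {
  cat(sprintf("Median RT: HC %.3f s, LC %.3f s (difference %.3f s)\n",
              x$class_medians["HC"], x$class_medians["LC"], x$difference))
  cat(sprintf("Rank-sum test HC vs LC: W = %g, p = %.3g\n",
              x$rank_test$statistic, x$rank_test$p.value))
  if (!is.null(x$condition_medians)) {
    cat("Condition medians (s):\n")
    print(round(x$condition_medians, 3))
  }
  invisible(x)
}
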