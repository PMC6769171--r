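#' Fit directed link-change networks from event-locked trials
#'
#' The package's central fit: starting from an event-locked trial set,
#' extracts band-power envelopes, computes the lag-maximized RMD for every
#' channel pair in the pre-stimulus baseline and in each sliding task
#' window, tests each link's task-vs-baseline change with a paired t test
#' corrected by the max-statistic permutation scheme, classifies the
#' significant links into increasing/decreasing directed networks, and
#' derives the network-formation timeline (t1, t2, t3).
#'
#' Each window family (all channel pairs within one task window) is
#' corrected separately; `correct_across_windows = TRUE` pools all windows
#' into a single family instead. The permutation seed for window `w` is
#' `seed + w` so stages can be re-run independently yet reproducibly.
#'
#' @param trials An `"eeg_trials"` object (all trials enter the pairing;
#'   subset to one condition's K trials beforehand, e.g. with
#'   [assign_conditions()]).
#' @param band `"alpha"` or `"beta"`.
#' @param target_rr Recurrence rate for the RMD (default 0.3).
#' @param tau_max Maximum RMD lag in seconds (default 0.2).
#' @param decimate Envelope decimation factor (default 10; see
#'   [extract_band_envelopes()]).
#' @param window_length,window_step,window_span Sliding task-window grid in
#'   seconds post-stimulus (defaults 1, 0.1, `c(0, 3)`).
#' @param baseline Baseline window relative to onset (default `c(-1, 0)`).
#' @param n_perm,alpha Permutation count and family-wise level.
#' @param seed Base seed for the permutation stage.
#' @param region_map Region parcellation for region degrees.
#' @param condition Optional condition label carried into the timeline.
#' @param correct_across_windows Pool all windows into one correction
#'   family.
#' @param envelopes Optional precomputed `band_power_set` (skips
#'   extraction; must match `trials`).
#' @return Object of class `"rmdnet"`: list with `links` (long-format
#'   per-window link table), `networks` (list of `"link_networks"` per
#'   window), `timeline` (`"network_timeline"`), `window_centers`, `band`,
#'   `condition`, `K`, `alpha`, `n_perm`, `call`.
#' @export
#' @examples
#' \donttest{
#' spec <- preset_frontal_hub_spec()
#' tr <- simulate_eeg_trials(spec, n_channels = 31, n_trials = 20, seed = 1)
#' fit <- rmdnet(tr, band = "beta", n_perm = 200, seed = 1)
#' print(fit)
#' }
rmdnet <- function(trials, band = "beta", target_rr = 0.3, tau_max = 0.2,
                   decimate = 10, window_length = 1, window_step = 0.1,
                   window_span = c(0, 3), baseline = c(-1, 0),
                   n_perm = 2000, alpha = 0.05, seed = NULL,
                   region_map = NULL, condition = NA,
                   correct_across_windows = FALSE, envelopes = NULL) {
  cl <- match.call()
  bp <- envelopes %||% extract_band_envelopes(trials, band, decimate = decimate)
  stopifnot(inherits(bp, "band_power_set"))
  n_ch <- dim(bp$env)[2]
  K <- dim(bp$env)[3]
  labels <- bp$channel_labels
  if (is.null(region_map)) {
    region_map <- if (n_ch == 31 && all(labels %in% default_montage()))
      default_region_map() else NULL
  }
  windows <- make_task_windows(window_length, window_step, window_span)
  W <- nrow(windows)
  pairs <- which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE)
  colnames(pairs) <- c("x", "y")
  L <- nrow(pairs)

  diffs <- array(NA_real_, dim = c(K, L, W))
  S_sign <- matrix(0L, L, W)
  dir_sign <- matrix(0L, L, W)
  for (p in seq_len(L)) {
    ls <- link_samples(bp, pair = pairs[p, ], baseline = baseline,
                       windows = windows, tau_max = tau_max,
                       target_rr = target_rr)
    for (w in seq_len(W)) {
      diffs[, p, w] <- ls$task[, w] - ls$baseline
      S_sign[p, w] <- sign(median(ls$task[, w]) - median(ls$baseline))
      ds <- sum(sign(ls$tau_task[, w]))
      dir_sign[p, w] <- if (ds >= 0) 1L else -1L   # tie -> x drives y
    }
  }
  centers <- rowMeans(windows)

  link_rows <- vector("list", W)
  networks <- vector("list", W)
  if (correct_across_windows) {
    flat <- matrix(diffs, nrow = K)                # K x (L*W)
    mt <- maxstat_correction(flat, n_perm = n_perm, alpha = alpha,
                             seed = if (is.null(seed)) NULL else seed + 1L)
    sig_all <- matrix(mt$significant, L, W)
    t_all <- matrix(mt$statistic, L, W)
    p_all <- matrix(mt$p, L, W)
  }
  for (w in seq_len(W)) {
    if (correct_across_windows) {
      res <- data.frame(x = pairs[, 1], y = pairs[, 2],
                        statistic = t_all[, w], p = p_all[, w],
                        significant = sig_all[, w])
    } else {
      mt <- maxstat_correction(diffs[, , w], n_perm = n_perm, alpha = alpha,
                               seed = if (is.null(seed)) NULL else seed + w)
      res <- data.frame(x = pairs[, 1], y = pairs[, 2],
                        statistic = mt$statistic, p = mt$p,
                        significant = mt$significant)
    }
    res$S <- S_sign[, w]
    res$direction <- dir_sign[, w]
    res$window <- centers[w]
    networks[[w]] <- classify_links(res, n_ch, labels)
    link_rows[[w]] <- res
  }
  links <- do.call(rbind, link_rows)
  tl <- if (!is.null(region_map))
    network_timeline(networks, centers, region_map, band = bp$band,
                     condition = condition)
  else {
    R <- vapply(networks, link_ratio, numeric(1))
    ex <- extract_timeline(R, centers)
    structure(list(times = centers, R = R, D = NULL, region_D = NULL,
                   t1 = ex$t1, t2 = ex$t2, t3 = ex$t3,
                   band = bp$band, condition = condition),
              class = "network_timeline")
  }
  structure(list(links = links, networks = networks, timeline = tl,
                 window_centers = centers, band = bp$band,
                 condition = condition, K = K, n_channels = n_ch,
                 channel_labels = labels, alpha = alpha, n_perm = n_perm,
                 target_rr = target_rr, call = cl),
            class = "rmdnet")
}

#' @export
print.rmdnet <- function(x, ...) {
  cat(sprintf("rmdnet fit: %s band, %d channels, K = %d trials, %d windows\n",
              x$band, x$n_channels, x$K, length(x$window_centers)))
  n_sig <- vapply(x$networks, function(nw) sum(nw$M_inc) + sum(nw$M_dec), numeric(1))
  cat(sprintf("  significant links: %d total across windows (max %d in one window)\n",
              sum(n_sig), max(n_sig)))
  print(x$timeline)
  invisible(x)
}

#' @export
summary.rmdnet <- function(object, ...) {
  per_win <- data.frame(
    window = object$window_centers,
    n_inc = vapply(object$networks, function(nw) sum(nw$M_inc), numeric(1)),
    n_dec = vapply(object$networks, function(nw) sum(nw$M_dec), numeric(1))
  )
  per_win$R <- object$timeline$R
  out <- list(band = object$band, condition = object$condition,
              K = object$K, alpha = object$alpha, n_perm = object$n_perm,
              per_window = per_win,
              t1 = object$timeline$t1, t2 = object$timeline$t2,
              t3 = object$timeline$t3,
              region_D = object$timeline$region_D)
  class(out) <- "summary.rmdnet"
  out
}

#' @export
print.summary.rmdnet <- function(x, ...) {
  cat(sprintf("rmdnet summary: %s band, K = %d, alpha = %g (%d permutations)\n",
              x$band, x$K, x$alpha, x$n_perm))
  cat(sprintf("  t1 = %s, t2 = %s, t3 = %s (s post-stimulus)\n",
              format(x$t1), format(x$t2), format(x$t3)))
  cat("Per-window link counts:\n")
  print(x$per_window, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.rmdnet <- function(x, ...) plot(x$timeline, ...)

#' Subset an EEG trial set
#'
#' @param trials An `"eeg_trials"` object.
#' @param which Trial indices or trial ids (logical, integer positions, or
#'   via `by_id = TRUE` trial_id values).
#' @param by_id Interpret `which` as `trial_id` values.
#' @return The subsetted `"eeg_trials"` object.
#' @export
subset_trials <- function(trials, which, by_id = FALSE) {
  stopifnot(inherits(trials, "eeg_trials"))
  idx <- if (by_id) match(which, trials$meta$trial_id) else which
  if (anyNA(idx)) stop("unknown trial id(s)")
  out <- trials
  out$data <- trials$data[, , idx, drop = FALSE]
  out$meta <- trials$meta[idx, , drop = FALSE]
  if (!is.null(trials$envelopes))
    out$envelopes <- lapply(trials$envelopes, function(a) a[, , idx, drop = FALSE])
  out
}
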