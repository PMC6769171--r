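#' Recurrence matrix of a scalar envelope series
#'
#' Binary matrix marking pairs of time points at which the series returns
#' within a threshold distance `epsilon` of an earlier value:
#' `Rm[i, j] = 1` iff `|E(t_i) - E(t_j)| <= epsilon`. By default `epsilon`
#' is chosen as the `target_rr` quantile of all pairwise distances
#' (fixed-recurrence-rate construction), which makes the marginal
#' recurrence densities comparable across trials and channels. No
#' time-delay embedding is used: the measure operates on the scalar
#' band-power series directly, and distances are plain absolute differences.
#'
#' @param E Numeric series (length >= 2).
#' @param target_rr Target recurrence rate in (0, 1); default 0.3 — sized for the short 1-s analysis windows (see the methods vignette).
#' @param epsilon Optional fixed threshold overriding the quantile rule.
#' @return 0/1 integer matrix with unit diagonal and attributes `epsilon`
#'   and `recurrence_rate` (achieved off-diagonal rate). A constant series
#'   yields an all-ones matrix with a degenerate-distance warning.
#' @export
#' @examples
#' recurrence_matrix(c(0, 1, 0, 2, 0, 3), epsilon = 0.5)
recurrence_matrix <- function(E, target_rr = 0.3, epsilon = NULL) {
  n <- length(E)
  if (n < 2) stop("series too short for a recurrence matrix")
  if (is.null(epsilon)) {
    if (target_rr <= 0 || target_rr >= 1) stop("target_rr must be in (0, 1)")
    d <- abs(outer(E, E, "-"))
    dv <- d[upper.tri(d)]
    if (all(dv == 0)) {
      warning("degenerate (constant) series: all pairwise distances are zero")
      epsilon <- 0
    } else {
      epsilon <- quantile(dv, target_rr, type = 7, names = FALSE)
    }
  } else {
    d <- abs(outer(E, E, "-"))
  }
  Rm <- (d <= epsilon) + 0L
  structure(Rm, epsilon = epsilon,
            recurrence_rate = mean(Rm[upper.tri(Rm)]))
}

#' Joint recurrence matrix
#'
#' Elementwise product of two recurrence matrices: entries mark time-point
#' pairs at which both processes recur simultaneously. Row means of the
#' result are the joint recurrence densities.
#'
#' @param Rx,Ry Equal-sized 0/1 matrices from [recurrence_matrix()].
#' @return 0/1 matrix `Rx * Ry`.
#' @export
joint_recurrence <- function(Rx, Ry) {
  if (!all(dim(Rx) == dim(Ry))) stop("recurrence matrices differ in shape")
  unclass(Rx * Ry)
}

#' RMD from precomputed recurrence matrices
#'
#' The recurrence-based measure of dependence: the log2 mean ratio of joint
#' to marginal recurrence densities,
#' `RMD = log2( (1/N) * sum_i Pj(i) / (Px(i) * Py(i)) )`, with densities the
#' row means of the recurrence and joint-recurrence matrices. With unit
#' diagonals every marginal density is >= 1/N, so the ratio is always
#' defined; any index with a zero marginal product would be excluded from
#' the mean.
#'
#' @param Rx,Ry 0/1 recurrence matrices of the two series.
#' @return RMD scalar: 0 in expectation under independence, positive under
#'   functional dependence.
#' @export
rmd_from_matrices <- function(Rx, Ry) {
  if (!all(dim(Rx) == dim(Ry))) stop("recurrence matrices differ in shape")
  Px <- rowMeans(Rx)
  Py <- rowMeans(Ry)
  Pj <- rowMeans(Rx * Ry)
  denom <- Px * Py
  keep <- denom > 0
  log2(mean(Pj[keep] / denom[keep]))
}

#' RMD between two envelope segments
#'
#' Builds fixed-recurrence-rate recurrence matrices for both series and
#' evaluates the recurrence-based measure of dependence.
#'
#' @param Ex,Ey Numeric series of equal length (>= 10).
#' @param target_rr Recurrence rate for the threshold construction (default 0.3).
#' @return RMD scalar.
#' @export
#' @examples
#' set.seed(1)
#' rmd_value(runif(50), runif(50))   # near 0 for independent series
rmd_value <- function(Ex, Ey, target_rr = 0.3) {
  if (length(Ex) != length(Ey)) stop("series must have equal length")
  if (length(Ex) < 10) stop("series too short: need N >= 10")
  rmd_from_matrices(recurrence_matrix(Ex, target_rr),
                    recurrence_matrix(Ey, target_rr))
}

# Lag visiting order used for the argmax tie rule: increasing |tau|,
# positive sign first, so ties resolve to the smallest |tau| and, between
# +tau and -tau, to the positive (x-drives-y) lag.
lag_visit_order <- function(tau_max) {
  as.integer(rbind(seq_len(tau_max), -seq_len(tau_max)))
}

#' Lagged RMD profile and coupling direction
#'
#' Evaluates the RMD over a grid of nonzero lags
#' `tau in [-tau_max, -1] union [1, tau_max]`: at lag `tau` the pairs
#' `(Ex(t_i), Ey(t_i + tau))` over the overlap of length `N - |tau|` are
#' scored. Zero lag is never evaluated — instantaneous dependence is
#' excluded by design as a guard against field-spread artifacts. The
#' maximizing lag `tau*` gives the coupling direction: `x` drives `y` when
#' `tau* > 0`, `y` drives `x` when `tau* < 0`. Ties are broken toward the
#' smallest `|tau|`; an exact tie between `+tau` and `-tau` picks the
#' positive lag and sets `ambiguous = TRUE`.
#'
#' @param Ex,Ey Numeric series of equal length.
#' @param tau_max Maximum lag in samples (>= 1; `N - tau_max` must be >= 10).
#' @param target_rr Recurrence rate.
#' @param engine `"cpp"` (default, compiled) or `"r"` (pure-R reference);
#'   both produce identical profiles.
#' @return Object of class `"rmd_profile"`: list with `lags`, `rmd`
#'   (profile in `lags` order), `tau_star`, `rmd_star`, `n`, `ambiguous`.
#' @export
#' @examples
#' e <- simulate_coupled_envelopes(200, lag = 5, seed = 1)
#' rmd_lagged(e$x, e$y, tau_max = 10)$tau_star
rmd_lagged <- function(Ex, Ey, tau_max, target_rr = 0.3,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  n <- length(Ex)
  if (length(Ey) != n) stop("series must have equal length")
  if (tau_max < 1) stop("tau_max must be >= 1")
  if (n - tau_max < 10) stop("window too short after shifting: need N - tau_max >= 10")
  lags <- c(-rev(seq_len(tau_max)), seq_len(tau_max))
  vals <- if (engine == "cpp") {
    .rmd_profile_cpp(Ex, Ey, lags, target_rr)
  } else {
    vapply(lags, function(tau) {
      a <- abs(tau)
      if (tau > 0) rmd_value(Ex[seq_len(n - a)], Ey[(a + 1):n], target_rr)
      else rmd_value(Ex[(a + 1):n], Ey[seq_len(n - a)], target_rr)
    }, numeric(1))
  }
  visit <- lag_visit_order(tau_max)
  vv <- vals[match(visit, lags)]
  best <- visit[which.max(vv)]          # first strict max in visit order
  rmd_star <- max(vv)
  ambiguous <- best > 0 && any(visit == -best) &&
    vals[match(-best, lags)] == rmd_star
  structure(list(lags = lags, rmd = vals, tau_star = best,
                 rmd_star = rmd_star, n = n, n_overlap = n - abs(best),
                 target_rr = target_rr, ambiguous = ambiguous),
            class = "rmd_profile")
}

#' @export
print.rmd_profile <- function(x, ...) {
  cat(sprintf("RMD profile over %d lags (N = %d): RMD* = %.4f at tau* = %+d%s\n",
              length(x$lags), x$n, x$rmd_star, x$tau_star,
              if (x$ambiguous) " (ambiguous sign)" else ""))
  cat(sprintf("  direction: %s\n",
              if (x$tau_star > 0) "x drives y" else "y drives x"))
  invisible(x)
}

#' @export
plot.rmd_profile <- function(x, ...) {
  graphics::plot(x$lags, x$rmd, type = "b", pch = 16,
                 xlab = expression(tau ~ "(samples)"), ylab = "RMD",
                 main = "Lagged RMD profile", ...)
  graphics::abline(v = x$tau_star, lty = 2)
  invisible(x)
}

#' Per-trial RMD samples for one channel pair
#'
#' For every trial of a band-power set, computes the lag-maximized RMD in
#' the baseline window and in each sliding task window, giving the paired
#' samples the link statistics operate on.
#'
#' @param bp A `band_power_set` (see [extract_band_envelopes()]).
#' @param pair Length-2 vector of channel indices or labels `(x, y)`.
#' @param baseline Baseline window in seconds relative to stimulus onset
#'   (default `c(-1, 0)`).
#' @param windows Two-column matrix of task-window `(start, end)` times in
#'   seconds relative to onset; default [make_task_windows()].
#' @param tau_max Maximum lag in seconds (default 0.2).
#' @param target_rr Recurrence rate.
#' @return List with `baseline` (K-vector of RMD*), `task` (K x W matrix),
#'   `tau_task` / `tau_baseline` (maximizing lags, samples at the envelope
#'   rate), `window_centers` (s), `pair`.
#' @export
link_samples <- function(bp, pair, baseline = c(-1, 0), windows = NULL,
                         tau_max = 0.2, target_rr = 0.3) {
  stopifnot(inherits(bp, "band_power_set"))
  if (is.null(windows)) windows <- make_task_windows()
  idx <- resolve_channels(pair, bp$channel_labels)
  fs <- bp$fs
  onset <- bp$onset_index
  n_samp <- dim(bp$env)[1]
  wlen_b <- round((baseline[2] - baseline[1]) * fs)
  wlen_t <- round((windows[1, 2] - windows[1, 1]) * fs)
  if (wlen_b != wlen_t)
    stop("baseline and task windows must have equal length")
  starts <- c(onset + round(baseline[1] * fs),
              onset + round(windows[, 1] * fs))   # 0-based
  if (any(starts < 0) || any(starts + wlen_b > n_samp))
    stop("window exceeds trial bounds")
  tau_samp <- max(1L, round(tau_max * fs))
  X <- bp$env[, idx[1], , drop = TRUE]
  Y <- bp$env[, idx[2], , drop = TRUE]
  if (is.null(dim(X))) { X <- matrix(X, ncol = 1); Y <- matrix(Y, ncol = 1) }
  sc <- .rmd_scan_cpp(X, Y, as.integer(starts), as.integer(wlen_b),
                      as.integer(tau_samp), target_rr)
  list(baseline = sc$rmd[, 1],
       task = sc$rmd[, -1, drop = FALSE],
       tau_baseline = sc$tau[, 1],
       tau_task = sc$tau[, -1, drop = FALSE],
       window_centers = rowMeans(windows),
       pair = idx)
}

#' Sliding task-window grid
#'
#' Windows of `length` seconds stepped by `step` over `span` (seconds
#' post-stimulus), labeled downstream by their centers. Defaults: 1-s
#' windows (equal to the baseline), 0.1-s step over \[0, 3\] s.
#'
#' @param length Window length (s).
#' @param step Step between window starts (s).
#' @param span Start of first window and end of last window (s post-onset).
#' @return Two-column matrix of `(start, end)` times.
#' @export
make_task_windows <- function(length = 1, step = 0.1, span = c(0, 3)) {
  starts <- seq(span[1], span[2] - length, by = step)
  cbind(start = starts, end = starts + length)
}

resolve_channels <- function(x, labels) {
  if (is.character(x)) {
    idx <- match(x, labels)
    if (anyNA(idx)) stop("unknown channel label(s): ",
                         paste(x[is.na(idx)], collapse = ", "))
    idx
  } else {
    x <- as.integer(x)
    if (any(x < 1 | x > base::length(labels)))
      stop("channel index out of range")
    x
  }
}
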