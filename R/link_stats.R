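DEGENERATE_T <- 1e6   # sentinel |t| for zero-variance paired differences

#' Paired t statistic for one link
#'
#' Standard paired t on the per-trial differences `RMD_t - RMD_b`. Links
#' whose differences have zero variance cannot produce a finite t; they are
#' flagged degenerate and assigned `sign(difference) * 1e6` so they are
#' reported, never silently significant or silently dropped.
#'
#' @param rmd_b,rmd_t Baseline and task RMD* samples, equal length K >= 5.
#' @return List: `statistic`, `df`, `degenerate`.
#' @export
paired_link_test <- function(rmd_b, rmd_t) {
  K <- length(rmd_b)
  if (length(rmd_t) != K) stop("samples must have equal length")
  if (K < 5) stop("need at least 5 paired samples")
  d <- rmd_t - rmd_b
  s <- sd(d)
  if (s == 0) {
    list(statistic = sign(mean(d)) * DEGENERATE_T, df = K - 1L,
         degenerate = TRUE)
  } else {
    list(statistic = mean(d) / (s / sqrt(K)), df = K - 1L, degenerate = FALSE)
  }
}

# Vectorized paired t over columns of a K x L difference matrix,
# zero-variance columns mapped to the degenerate sentinel.
paired_t_columns <- function(D) {
  K <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - K * m^2) / (K - 1)
  v[v < 0] <- 0
  t <- ifelse(v == 0, sign(m) * DEGENERATE_T, m / sqrt(v / K))
  list(statistic = t, degenerate = v == 0)
}

#' Max-statistic permutation correction for a family of paired tests
#'
#' Family-wise error control over all links tested in one window family.
#' Under the null (baseline and task exchangeable within a trial) the sign
#' of each trial's difference is arbitrary, so the permutation null is
#' built by random sign-flips applied per trial — the same flip across all
#' links of a permutation, preserving the links' spatial correlation. For
#' each permutation the maximum |t| over the family is recorded; a link is
#' significant when its corrected p-value
#' `(1 + #permutations with max|t| >= |t_obs|) / (n_perm + 1)`
#' falls below `alpha`.
#'
#' @param diffs K x L matrix of per-trial differences (`RMD_t - RMD_b`),
#'   one column per link in the family.
#' @param n_perm Number of permutations (>= 100; default 2000).
#' @param alpha Two-sided family-wise level (default 0.05).
#' @param seed Seed for the sign-flip draws.
#' @return Object of class `"link_test"`: list with `statistic` (observed
#'   t per link), `p` (corrected p), `significant` (logical),
#'   `degenerate`, `threshold` (empirical `1 - alpha` quantile of the
#'   max-|t| null), `n_perm`, `alpha`.
#' @export
maxstat_correction <- function(diffs, n_perm = 2000, alpha = 0.05, seed = NULL) {
  diffs <- as.matrix(diffs)
  K <- nrow(diffs)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if ((n_perm + 1) * alpha < 1)
    stop("n_perm too small to resolve the requested alpha quantile")
  obs <- paired_t_columns(diffs)
  local_seed(seed, {
    S <- matrix(sample(c(-1, 1), K * n_perm, replace = TRUE), K, n_perm)
    M <- crossprod(S, diffs) / K                     # n_perm x L means
    ss <- matrix(colSums(diffs^2), n_perm, ncol(diffs), byrow = TRUE)
    V <- (ss - K * M^2) / (K - 1)
    V[V < 0] <- 0
    Tm <- abs(M) / sqrt(V / K)
    Tm[V == 0] <- DEGENERATE_T
    max_null <- apply(Tm, 1, max)
    p <- vapply(abs(obs$statistic),
                function(t0) (1 + sum(max_null >= t0)) / (n_perm + 1),
                numeric(1))
    structure(list(statistic = obs$statistic, p = p,
                   significant = p < alpha, degenerate = obs$degenerate,
                   threshold = quantile(max_null, 1 - alpha, names = FALSE),
                   n_perm = n_perm, alpha = alpha),
              class = "link_test")
  })
}

#' @export
print.link_test <- function(x, ...) {
  cat(sprintf("Max-statistic permutation test: %d links, %d permutations, alpha = %g\n",
              length(x$statistic), x$n_perm, x$alpha))
  cat(sprintf("  significant: %d; max-|t| null threshold %.3f\n",
              sum(x$significant), x$threshold))
  invisible(x)
}

#' Classify significant links into increasing / decreasing networks
#'
#' Builds the directed binary matrices `M_inc` and `M_dec` for one task
#' window from per-link test results. A significant link with
#' `S = sign(median(RMD_t) - median(RMD_b)) > 0` enters `M_inc`, `S < 0`
#' enters `M_dec`; `S = 0` on a significant link is flagged and excluded.
#' The direction (row = source channel) comes from the majority sign of
#' the per-trial maximizing lags `tau*` in that window: positive majority
#' means the first channel of the pair drives the second.
#'
#' @param results Data frame with one row per tested (unordered) pair:
#'   columns `x`, `y` (channel indices), `significant`, `S`
#'   (sign of the median difference), `direction` (+1: x drives y,
#'   -1: y drives x).
#' @param n_channels Number of channels (matrix dimension).
#' @param labels Optional channel labels for dimnames.
#' @return List of class `"link_networks"`: `M_inc`, `M_dec` (0/1 matrices
#'   with zero diagonal), `flagged` (rows excluded for S = 0).
#' @export
classify_links <- function(results, n_channels, labels = NULL) {
  M_inc <- matrix(0L, n_channels, n_channels)
  M_dec <- matrix(0L, n_channels, n_channels)
  if (!is.null(labels)) dimnames(M_inc) <- dimnames(M_dec) <- list(labels, labels)
  sig <- results[results$significant, , drop = FALSE]
  flagged <- sig[sig$S == 0, , drop = FALSE]
  sig <- sig[sig$S != 0, , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    src <- if (sig$direction[r] >= 0) sig$x[r] else sig$y[r]
    tgt <- if (sig$direction[r] >= 0) sig$y[r] else sig$x[r]
    if (sig$S[r] > 0) M_inc[src, tgt] <- 1L else M_dec[src, tgt] <- 1L
  }
  structure(list(M_inc = M_inc, M_dec = M_dec, flagged = flagged),
            class = "link_networks")
}

#' @export
print.link_networks <- function(x, ...) {
  cat(sprintf("Link-change networks: %d increasing, %d decreasing link(s) over %d channels\n",
              sum(x$M_inc), sum(x$M_dec), nrow(x$M_inc)))
  if (nrow(x$flagged))
    cat("  ", nrow(x$flagged), "significant link(s) excluded for S = 0\n")
  invisible(x)
}
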