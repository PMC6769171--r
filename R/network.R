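#' Ratio of increasing to decreasing link counts
#'
#' `R = sum(M_inc) / sum(M_dec)`. With no decreasing links but at least one
#' increasing link the ratio is `Inf` (which still counts as `R > 1` for
#' crossing detection); with neither it is `NaN` (undefined, never a
#' crossing).
#'
#' @param nets A `"link_networks"` object, or `M_inc` with `M_dec` given
#'   separately.
#' @param M_dec Decreasing-link matrix when `nets` is a plain matrix.
#' @return Numeric scalar (possibly `Inf` or `NaN`).
#' @export
link_ratio <- function(nets, M_dec = NULL) {
  if (inherits(nets, "link_networks")) {
    inc <- sum(nets$M_inc); dec <- sum(nets$M_dec)
  } else {
    inc <- sum(nets); dec <- sum(M_dec)
  }
  if (dec == 0) {
    if (inc == 0) NaN else Inf
  } else inc / dec
}

#' Outgoing node degree
#'
#' Number of increasing links emanating from each channel: the row sums of
#' `M_inc`.
#'
#' @param M_inc Square binary matrix (row = source).
#' @return Named numeric vector of out-degrees.
#' @export
out_degree <- function(M_inc) {
  if (!is.matrix(M_inc) || nrow(M_inc) != ncol(M_inc))
    stop("M_inc must be a square matrix")
  if (!all(M_inc %in% c(0, 1))) stop("M_inc must be binary")
  rowSums(M_inc)
}

#' Region-averaged outgoing degree
#'
#' Mean out-degree over the channels of each scalp region — the summary
#' used to quantify a cortical area's driving role.
#'
#' @param D_i Out-degree vector named by channel label (or positional when
#'   `labels` given).
#' @param map Region map (list region -> channel labels),
#'   e.g. [default_region_map()].
#' @param labels Channel labels for `D_i` when it is unnamed.
#' @return Named numeric vector, one mean degree per region.
#' @export
region_degree <- function(D_i, map, labels = NULL) {
  if (is.null(names(D_i))) {
    if (is.null(labels)) stop("D_i must be named or labels supplied")
    names(D_i) <- labels
  }
  out <- vapply(map, function(chs) {
    if (!length(chs)) stop("empty region in region map")
    miss <- setdiff(chs, names(D_i))
    if (length(miss)) stop("region channels missing from D_i: ",
                           paste(miss, collapse = ", "))
    mean(D_i[chs])
  }, numeric(1))
  out
}

#' Extract the network-formation timeline (t1, t2, t3)
#'
#' From the link-ratio series `R(t)` over task windows: `t1` is the
#' earliest window time at which `R > 1` holds for at least 2 consecutive
#' windows (the debounce suppresses single-window noise); `t3` is the time
#' of the maximum `R` on `[t1, end]` (earliest on ties, `Inf` allowed);
#' `t2 = t1 + (t3 - t1)/2` is the midpoint of the formation interval. If
#' `R` never crosses unity for two consecutive windows, all three are `NA`.
#'
#' @param R Numeric link-ratio series (may contain `Inf`/`NaN` sentinels).
#' @param times Window center times (s post-onset), same length as `R`.
#' @return List: `t1`, `t2`, `t3` (seconds, `NA` when undefined).
#' @export
#' @examples
#' extract_timeline(c(0.5, 0.8, 1.2, 1.5, 2.0, 1.8), seq(0.1, 0.6, by = 0.1))
extract_timeline <- function(R, times) {
  if (length(R) != length(times)) stop("R and times must have equal length")
  if (length(R) < 3) stop("need at least 3 windows")
  above <- !is.na(R) & !is.nan(R) & R > 1        # Inf > 1 is TRUE
  start <- NA_integer_
  for (i in seq_len(length(R) - 1L))
    if (above[i] && above[i + 1L]) { start <- i; break }
  if (is.na(start)) return(list(t1 = NA_real_, t2 = NA_real_, t3 = NA_real_))
  t1 <- times[start]
  seg <- R[start:length(R)]
  seg[is.nan(seg)] <- -Inf
  i3 <- start + which.max(seg) - 1L               # earliest max on ties
  t3 <- times[i3]
  list(t1 = t1, t2 = t1 + (t3 - t1) / 2, t3 = t3)
}

#' Build a network timeline from per-window link networks
#'
#' Computes `R(t)`, per-channel out-degrees, region-averaged degrees and
#' the `t1`/`t2`/`t3` instants for one band/condition.
#'
#' @param nets List of `"link_networks"`, one per task window.
#' @param times Window center times (s post-onset).
#' @param region_map Region parcellation (default [default_region_map()]).
#' @param band,condition Labels carried for reporting.
#' @return Object of class `"network_timeline"`: `times`, `R`, `D`
#'   (channels x windows out-degree matrix), `region_D`
#'   (regions x windows), `t1`, `t2`, `t3`, `band`, `condition`.
#' @export
network_timeline <- function(nets, times, region_map = default_region_map(),
                             band = NA, condition = NA) {
  stopifnot(length(nets) == length(times))
  labels <- rownames(nets[[1]]$M_inc)
  R <- vapply(nets, link_ratio, numeric(1))
  D <- vapply(nets, function(nw) out_degree(nw$M_inc), numeric(nrow(nets[[1]]$M_inc)))
  if (!is.null(labels)) rownames(D) <- labels
  region_D <- vapply(seq_along(nets), function(w)
    region_degree(D[, w], region_map, labels = labels),
    numeric(length(region_map)))
  rownames(region_D) <- names(region_map)
  tl <- extract_timeline(R, times)
  structure(list(times = times, R = R, D = D, region_D = region_D,
                 t1 = tl$t1, t2 = tl$t2, t3 = tl$t3,
                 band = band, condition = condition),
            class = "network_timeline")
}

#' @export
print.network_timeline <- function(x, ...) {
  cat(sprintf("Network timeline (%s band%s): %d windows\n",
              x$band, if (is.na(x$condition)) "" else paste0(", ", x$condition),
              length(x$times)))
  if (is.na(x$t1)) {
    cat("  R never crosses unity for 2 consecutive windows: t1/t2/t3 undefined\n")
  } else {
    cat(sprintf("  t1 = %.2f s, t2 = %.2f s, t3 = %.2f s post-stimulus\n",
                x$t1, x$t2, x$t3))
  }
  invisible(x)
}

#' @export
plot.network_timeline <- function(x, ...) {
  Rplot <- x$R
  finite_max <- max(Rplot[is.finite(Rplot)], 1, na.rm = TRUE)
  Rplot[is.infinite(Rplot)] <- finite_max * 1.2
  graphics::plot(x$times, Rplot, type = "l", lwd = 2,
                 xlab = "time post-stimulus (s)",
                 ylab = "R (increasing / decreasing links)",
                 main = sprintf("Network formation, %s band", x$band), ...)
  graphics::abline(h = 1, lty = 3)
  if (!is.na(x$t1)) {
    graphics::abline(v = c(x$t1, x$t3), lty = 2, col = "gray40")
    graphics::mtext(c("t1", "t3"), at = c(x$t1, x$t3), side = 3, line = 0, cex = 0.8)
  }
  invisible(x)
}

#' Tidy timeline-vs-reaction-time report
#'
#' Assembles, per condition, the network-formation instants per band
#' together with the condition's median RT and the lag `RT - t1(beta)` —
#' the long-format table a group-level repeated-measures analysis consumes.
#' No inferential statistics are computed here.
#'
#' @param timelines List of `"network_timeline"` objects (each carrying
#'   `band` and `condition` labels).
#' @param median_rt Named numeric vector of median RT (s) per condition.
#' @param subject Subject identifier for the table (default `"S1"`).
#' @return `data.frame` with columns `subject`, `condition`, `t1_alpha`,
#'   `t1_beta`, `t2_beta`, `t3_beta`, `median_rt`, `rt_minus_t1_beta`.
#'   Conditions with no timeline are omitted with a warning.
#' @export
timeline_vs_rt_report <- function(timelines, median_rt, subject = "S1") {
  conds <- names(median_rt)
  rows <- lapply(conds, function(cond) {
    tls <- Filter(function(tl) identical(tl$condition, cond), timelines)
    if (!length(tls)) {
      warning("no timeline for condition ", cond, "; row omitted")
      return(NULL)
    }
    get_band <- function(b) Filter(function(tl) identical(tl$band, b), tls)
    a <- get_band("alpha"); b <- get_band("beta")
    t1a <- if (length(a)) a[[1]]$t1 else NA_real_
    t1b <- if (length(b)) b[[1]]$t1 else NA_real_
    data.frame(subject = subject, condition = cond,
               t1_alpha = t1a, t1_beta = t1b,
               t2_beta = if (length(b)) b[[1]]$t2 else NA_real_,
               t3_beta = if (length(b)) b[[1]]$t3 else NA_real_,
               median_rt = unname(median_rt[cond]),
               rt_minus_t1_beta = unname(median_rt[cond]) - t1b,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
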