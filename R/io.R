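pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a continuous multichannel recording as EDF
#'
#' Minimal European Data Format writer: 16-bit integer samples in 1-s data
#' records, per-channel physical scaling from the data range. Events are
#' not embedded (no EDF+ annotation stream); pair the file with a CSV
#' events table ([write_events()]). The recording is zero-padded to a whole
#' number of records.
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate (Hz, integer).
#' @param labels Channel labels (<= 16 characters each).
#' @param path Output file path.
#' @param phys_dim Physical dimension string (default "uV").
#' @return Invisibly, `path`.
#' @export
write_edf <- function(data, fs, labels = rownames(data), path,
                      phys_dim = "uV") {
  stopifnot(is.matrix(data), fs == as.integer(fs))
  ns <- nrow(data)
  labels <- labels %||% sprintf("Ch%02d", seq_len(ns))
  n_rec <- ceiling(ncol(data) / fs)
  pad <- n_rec * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, ns, pad))
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80), pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(ns, 4),
    paste(pad_field(labels, 16), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(pad_field(rep(phys_dim, ns), 8), collapse = ""),
    paste(pad_field(formatC(pmin_, digits = 5, format = "g"), 8), collapse = ""),
    paste(pad_field(formatC(pmax_, digits = 5, format = "g"), 8), collapse = ""),
    paste(pad_field(rep(dmin, ns), 8), collapse = ""),
    paste(pad_field(rep(dmax, ns), 8), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(pad_field(rep(fs, ns), 8), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # physical values as re-read from the 8-char header fields, so the
  # round-trip error is bounded by digitization, not header truncation
  pmin_h <- as.numeric(formatC(pmin_, digits = 5, format = "g"))
  pmax_h <- as.numeric(formatC(pmax_, digits = 5, format = "g"))
  scale <- (pmax_h - pmin_h) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((pmin(pmax(data[ch, cols], pmin_h[ch]), pmax_h[ch]) -
                      pmin_h[ch]) / scale[ch]) + dmin
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_header_fields <- function(raw, offsets, widths) {
  mapply(function(o, w) trimws(rawToChar(raw[(o + 1):(o + w)])),
         offsets, widths)
}

#' Read an EDF recording
#'
#' Reads a plain EDF file (as written by [write_edf()] or standard
#' acquisition software without EDF+ annotation streams), reconstructing
#' physical values from the per-channel scaling. All channels must share
#' one sampling rate.
#'
#' @param path EDF file path.
#' @return List: `data` (channels x samples), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 256) stop("truncated EDF: file ends at byte ",
                                  max(sz, 0), ", header needs 256")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256)
  n_rec <- as.integer(rawToChar(hdr[237:244]))
  dur <- as.numeric(rawToChar(hdr[245:252]))
  ns <- as.integer(rawToChar(hdr[253:256]))
  if (is.na(ns) || ns < 1) stop("unparseable EDF header: bad signal count")
  sig_hdr_len <- 256 * ns
  if (sz < 256 + sig_hdr_len)
    stop("truncated EDF: signal headers need ", 256 + sig_hdr_len,
         " bytes, file ends at byte ", sz)
  sh <- readBin(con, "raw", sig_hdr_len)
  fld <- function(start, width) {
    vapply(seq_len(ns), function(i) {
      o <- start + (i - 1) * width
      trimws(rawToChar(sh[(o + 1):(o + width)]))
    }, character(1))
  }
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(ns * (16 + 80 + 8), 8))
  pmax_ <- as.numeric(fld(ns * (16 + 80 + 8 + 8), 8))
  dmin <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8), 8))
  dmax <- as.numeric(fld(ns * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fld(ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported")
  expected <- 256 + sig_hdr_len + n_rec * sum(spr) * 2
  if (sz < expected)
    stop("truncated EDF: expected ", expected, " bytes, file ends at byte ", sz)
  data <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[ch], size = 2, endian = "little")
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (dig - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  rownames(data) <- labels
  list(data = data, fs = spr[1] / dur, labels = labels)
}

#' Write / read a delimited channel-by-time matrix
#'
#' CSV with one column per channel (header = channel labels, order
#' preserved), one row per sample.
#'
#' @param data Channels x samples matrix.
#' @param labels Channel labels.
#' @param path File path.
#' @return `write_eeg_delimited`: invisibly `path`.
#' @export
write_eeg_delimited <- function(data, labels = rownames(data), path) {
  labels <- labels %||% sprintf("Ch%02d", seq_len(nrow(data)))
  df <- as.data.frame(t(data))
  names(df) <- labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_delimited
#' @export
read_eeg_delimited <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(data = t(as.matrix(df)), labels = names(df))
}

#' Read a continuous recording (EDF or delimited)
#'
#' Dispatches on `format` (or file extension with `"auto"`). Delimited
#' files carry no sampling rate, so `fs` must be supplied for them.
#'
#' @param path File path.
#' @param format `"auto"`, `"edf"` or `"delimited"`.
#' @param fs Sampling rate (Hz); required for delimited input, checked
#'   against the header for EDF when given.
#' @return List: `data` (channels x samples), `fs`, `labels`.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "delimited"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") {
    out <- read_edf(path)
    if (!is.null(fs) && out$fs != fs)
      stop("sampling-rate mismatch: file says ", out$fs, " Hz, config says ", fs)
    out
  } else {
    if (is.null(fs)) stop("fs must be supplied for delimited input")
    d <- read_eeg_delimited(path)
    list(data = d$data, fs = fs, labels = d$labels)
  }
}

#' Write / read a trial events table
#'
#' Fixed-column CSV: `trial_id`, `onset_sample` (0-based), `g`, `rt_s`,
#' plus any further behavioral columns present.
#'
#' @param events Data frame with at least the fixed columns.
#' @param path File path.
#' @return `write_events`: invisibly `path`; `read_events`: the data frame.
#' @export
write_events <- function(events, path) {
  need <- c("trial_id", "onset_sample", "g", "rt_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events table missing column(s): ",
                         paste(miss, collapse = ", "))
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.csv(path)
  need <- c("trial_id", "onset_sample", "g", "rt_s")
  miss <- setdiff(need, names(ev))
  if (length(miss)) stop("events table missing column(s): ",
                         paste(miss, collapse = ", "))
  ev
}
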