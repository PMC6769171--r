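#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' list, with one explicit seed per stochastic stage (simulation, condition
#' subsampling, permutation testing) so stages can be re-run independently.
#' All time coordinates are seconds relative to stimulus onset; windows are
#' closed on the left and open on the right.
#'
#' @param n_channels,fs,n_trials,snr Simulator geometry: channel count,
#'   sampling rate (Hz), session trial count, carrier-to-noise variance
#'   ratio.
#' @param coupling A [coupling_spec()], or `NULL` for uncoupled data.
#' @param model A [behavioral_model()].
#' @param amp_threshold Artifact-rejection amplitude threshold
#'   (`NULL` = skip rejection).
#' @param K Trials retained per condition.
#' @param bands Bands analyzed.
#' @param target_rr,tau_max,decimate RMD parameters (rate, max lag s,
#'   envelope decimation).
#' @param window_length,window_step,window_span,baseline Window grid (s).
#' @param n_perm,alpha Permutation test parameters.
#' @param seed_sim,seed_subsample,seed_perm Stage seeds.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_channels = 31, fs = 250, n_trials = 350,
                            snr = 50, coupling = NULL,
                            model = behavioral_model(),
                            amp_threshold = NULL, K = 20,
                            bands = c("beta", "alpha"),
                            target_rr = 0.3, tau_max = 0.2, decimate = 10,
                            window_length = 1, window_step = 0.1,
                            window_span = c(0, 3), baseline = c(-1, 0),
                            n_perm = 2000, alpha = 0.05,
                            seed_sim = 1, seed_subsample = 2, seed_perm = 3) {
  cfg <- list(n_channels = n_channels, fs = fs, n_trials = n_trials,
              snr = snr, coupling = coupling, model = model,
              amp_threshold = amp_threshold, K = K, bands = bands,
              target_rr = target_rr, tau_max = tau_max, decimate = decimate,
              window_length = window_length, window_step = window_step,
              window_span = window_span, baseline = baseline,
              n_perm = n_perm, alpha = alpha,
              seed_sim = seed_sim, seed_subsample = seed_subsample,
              seed_perm = seed_perm)
  class(cfg) <- "pipeline_config"
  cfg
}

# FNV-1a hash of the serialized config: a short provenance stamp written
# into every pipeline output so mismatched artifacts refuse to combine.
config_hash <- function(cfg) {
  raw <- charToRaw(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in as.integer(raw)) {
    # xor on the low byte, then multiply mod 2^32 in 16-bit halves so all
    # intermediates stay exactly representable in doubles
    h <- h - h %% 256 + bitwXor(as.integer(h %% 256), b)
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Simulates a session (behavioral table + event-locked EEG trials),
#' optionally rejects high-amplitude trials, assigns SH1/SH2/SE2 conditions
#' from RT percentiles, fits the directed link-change networks per
#' condition and band, and assembles the timeline-vs-RT report. Fully
#' deterministic under the config's stage seeds; every written artifact
#' carries the config hash.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report, link tables,
#'   per-window adjacency matrices and timeline JSON are written there.
#' @param verbose Print stage progress.
#' @return Object of class `"rmdnet_study"`: list with `behavior`,
#'   `assignment`, `fits` (list indexed `condition.band`), `report`,
#'   `rt_summary`, `config`, `config_hash`, `log` (trial counts per stage).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- config$coupling %||%
    coupling_spec(data.frame(source = integer(), target = integer(),
                             lag = integer(), gain = numeric(),
                             polarity = character()), 0, "beta")

  say("simulating %d trials (%d channels, %g Hz)", config$n_trials,
      config$n_channels, config$fs)
  trials <- simulate_eeg_trials(spec, model = config$model,
                                n_channels = config$n_channels,
                                fs = config$fs, n_trials = config$n_trials,
                                snr = config$snr, seed = config$seed_sim)
  log <- list(n_simulated = config$n_trials)
  if (!is.null(config$amp_threshold)) {
    trials <- reject_artifact_trials(trials, config$amp_threshold)
    log$n_rejected <- config$n_trials - dim(trials$data)[3]
  }
  log$n_usable <- dim(trials$data)[3]

  assignment <- assign_conditions(trials$meta,
                                  high_g_set = config$model$g_high,
                                  low_g_set = config$model$g_low,
                                  K = config$K, seed = config$seed_subsample)
  rt_sum <- summarize_rts(trials$meta, assignment)
  conds <- c("SH1", "SH2", "SE2")
  fits <- list()
  sig_log <- list()
  for (cond in conds) {
    ids <- assignment$trial_id[assignment$label == cond]
    sub <- subset_trials(trials, ids, by_id = TRUE)
    for (band in config$bands) {
      say("fitting %s / %s band (K = %d)", cond, band, config$K)
      fit <- rmdnet(sub, band = band, target_rr = config$target_rr,
                    tau_max = config$tau_max, decimate = config$decimate,
                    window_length = config$window_length,
                    window_step = config$window_step,
                    window_span = config$window_span,
                    baseline = config$baseline,
                    n_perm = config$n_perm, alpha = config$alpha,
                    seed = config$seed_perm, condition = cond)
      fits[[paste(cond, band, sep = ".")]] <- fit
      sig_log[[paste(cond, band, sep = ".")]] <-
        vapply(fit$networks, function(nw) sum(nw$M_inc) + sum(nw$M_dec),
               numeric(1))
    }
  }
  log$significant_links_per_window <- sig_log

  timelines <- lapply(fits, function(f) f$timeline)
  med_rt <- vapply(conds, function(cond) {
    ids <- assignment$trial_id[assignment$label == cond]
    median(trials$meta$rt_s[trials$meta$trial_id %in% ids])
  }, numeric(1))
  report <- timeline_vs_rt_report(timelines, med_rt)

  study <- structure(list(behavior = trials$meta, assignment = assignment,
                          fits = fits, report = report, rt_summary = rt_sum,
                          config = config, config_hash = hash, log = log),
                     class = "rmdnet_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.rmdnet_study <- function(x, ...) {
  cat(sprintf("rmdnet study [config %s]: %d usable trials, %d fits\n",
              x$config_hash, x$log$n_usable, length(x$fits)))
  print(x$rt_summary)
  cat("\nTimeline report:\n")
  print(x$report, row.names = FALSE, digits = 3)
  invisible(x)
}

write_with_hash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' Write study artifacts to disk
#'
#' Persists the report and per-fit link tables as CSV (with a config-hash
#' header line), per-window increasing/decreasing adjacency matrices as
#' delimited text with channel-label headers, and the timelines as JSON.
#'
#' @param study An `"rmdnet_study"`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- study$config_hash
  paths <- character()
  p <- file.path(out_dir, "report.csv")
  write_with_hash(study$report, p, hash)
  paths <- c(paths, p)
  tl_list <- lapply(study$fits, function(f) {
    tl <- f$timeline
    list(condition = tl$condition, band = tl$band,
         t1 = tl$t1, t2 = tl$t2, t3 = tl$t3,
         windows = tl$times, R = tl$R,
         region_D = if (!is.null(tl$region_D)) as.data.frame(t(tl$region_D)))
  })
  p <- file.path(out_dir, "timelines.json")
  jsonlite::write_json(list(config_hash = hash, timelines = tl_list), p,
                       auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  paths <- c(paths, p)
  for (nm in names(study$fits)) {
    f <- study$fits[[nm]]
    p <- file.path(out_dir, sprintf("links_%s.csv", nm))
    write_with_hash(f$links, p, hash)
    paths <- c(paths, p)
    nd <- file.path(out_dir, "networks")
    dir.create(nd, showWarnings = FALSE)
    for (w in seq_along(f$networks)) {
      for (kind in c("M_inc", "M_dec")) {
        pw <- file.path(nd, sprintf("%s_w%02d_%s.csv", nm, w, kind))
        write_with_hash(as.data.frame(f$networks[[w]][[kind]]), pw, hash)
        paths <- c(paths, pw)
      }
    }
  }
  invisible(paths)
}

#' Read a pipeline artifact, enforcing config-hash provenance
#'
#' Reads a CSV written by [write_study()] and checks its config-hash header
#' against `expect_hash`; mismatched artifacts refuse to combine.
#'
#' @param path CSV path.
#' @param expect_hash Hash the artifact must carry (`NULL` = no check).
#' @return The data frame, with attribute `config_hash`.
#' @export
read_study_csv <- function(path, expect_hash = NULL) {
  first <- readLines(path, n = 1)
  hash <- sub("^# config_hash: ", "", first)
  if (!is.null(expect_hash) && !identical(hash, expect_hash))
    stop("config hash mismatch: artifact ", hash, " vs expected ", expect_hash)
  df <- read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- hash
  df
}
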