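test_that("band-pass chain attenuates out-of-band and passes in-band tones", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  slow <- sin(2 * pi * 0.1 * t)
  y <- bandpass_notch_filter(slow, fs)
  expect_lt(max(abs(y[mid])) / 1, 10^(-20 / 20))   # >= 20 dB down
  tone <- sin(2 * pi * 10 * t)
  y10 <- bandpass_notch_filter(tone, fs)
  expect_equal(max(abs(y10[mid])), 1, tolerance = 0.05)
  expect_equal(bandpass_notch_filter(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass_notch_filter(tone, fs = 150, lp = 100), "low")
})

test_that("notch suppresses the line frequency", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  y <- bandpass_notch_filter(sin(2 * pi * 50 * t), fs)
  expect_lt(max(abs(y[(3 * fs):(7 * fs)])), 0.05)
})

test_that("segmentation cuts 1 s before and 3 s after each onset", {
  fs <- 250
  cont <- matrix(seq_len(2 * 5000), nrow = 2, byrow = TRUE)
  ev <- data.frame(trial_id = 1:2, onset_sample = c(500, 2000),
                   g = c(0, 1), rt_s = c(0.8, 1.2))
  tr <- segment_trials(cont, fs, ev)
  expect_equal(dim(tr$data), c(2, 1000, 2))
  # 0-based onset 500 spans samples [250, 1250)
  expect_equal(tr$data[1, , 1], 251:1250)
  expect_equal(tr$meta$trial_id, 1:2)
})

test_that("onsets too close to the record edge are dropped with a warning", {
  cont <- matrix(rnorm(2 * 2000), nrow = 2)
  ev <- data.frame(trial_id = 1:2, onset_sample = c(100, 600),
                   g = 0, rt_s = 1)
  expect_warning(tr <- segment_trials(cont, 250, ev), "dropped")
  expect_equal(dim(tr$data)[3], 1)
  expect_equal(tr$meta$trial_id, 2)
})

test_that("artifact rejection removes exactly the spiking trials", {
  spec <- coupling_spec(data.frame(source = 1, target = 2, lag = 5, gain = 1,
                                   polarity = "increasing"))
  tr <- simulate_eeg_trials(spec, n_channels = 3, n_trials = 5, seed = 21)
  expect_equal(dim(reject_artifact_trials(tr, Inf)$data), dim(tr$data))
  spiked <- tr
  spiked$data[2, 500, 3] <- 10 * max(abs(tr$data))
  out <- reject_artifact_trials(spiked, 5 * max(abs(tr$data)))
  expect_equal(dim(out$data)[3], 4)
  expect_equal(attr(out, "rejected")$trial_id, 3)
  expect_error(reject_artifact_trials(tr, 1e-12), "empty")
})

test_that("rejection rate matches a brute-force count at a quantile threshold", {
  spec <- coupling_spec(data.frame(source = integer(), target = integer(),
                                   lag = integer(), gain = numeric(),
                                   polarity = character()), 0, "beta")
  tr <- simulate_eeg_trials(spec, n_channels = 2, fs = 250, n_trials = 50,
                            seed = 31)
  peaks <- apply(abs(tr$data), 3, max)
  thr <- quantile(peaks, 0.98, names = FALSE)
  out <- reject_artifact_trials(tr, thr)
  expect_equal(dim(out$data)[3], sum(peaks <= thr))
})

test_that("condition assignment reproduces the percentile oracle", {
  # 100 evenly spaced HC RTs 0.5..2.48 plus an LC block below the HC median
  rt_hc <- seq(0.5, 2.48, length.out = 100)
  beh <- data.frame(trial_id = 1:200, g = rep(c(0.5, 0), each = 100),
                    rt_s = c(rt_hc, seq(0.4, 1.6, length.out = 100)))
  asn <- assign_conditions(beh, high_g_set = 0.5, low_g_set = 0,
                           K = 20, seed = 1)
  el <- attr(asn, "eligible")
  # oracle: sort-and-interpolate (linear between closest ranks)
  lo <- bf_percentile(rt_hc, 0.75)
  hi <- bf_percentile(rt_hc, 0.975)
  expect_equal(sort(el$SH1), which(rt_hc >= lo & rt_hc <= hi))
  expect_equal(sort(el$SH1), 76:97)
  # SH2/SE2 interval = [median(LC), median(HC)], endpoints inclusive
  m_lc <- bf_percentile(beh$rt_s[101:200], 0.5)
  m_hc <- bf_percentile(rt_hc, 0.5)
  expect_equal(sort(el$SH2), which(rt_hc >= m_lc & rt_hc <= m_hc))
})

test_that("assignment invariants hold on random behavioral tables", {
  for (s in 1:30) {
    b <- simulate_rts(behavioral_model(), 400, seed = 500 + s)
    asn <- tryCatch(assign_conditions(b, K = 10, seed = s),
                    error = function(e) NULL)
    if (is.null(asn)) next
    tab <- table(asn$label)
    expect_equal(unname(tab[c("SH1", "SH2", "SE2")]), rep(10L, 3),
                 ignore_attr = TRUE)
    merged <- merge(b, as.data.frame(asn), by = "trial_id")
    expect_true(all(merged$g[merged$label %in% c("SH1", "SH2")] %in%
                      c(0.4, 0.45, 0.55, 0.6)))
    expect_true(all(merged$g[merged$label == "SE2"] %in% c(0, 0.15, 0.85, 1)))
  }
})

test_that("subsampling is reproducible and shortfalls are named", {
  b <- simulate_rts(behavioral_model(), 400, seed = 77)
  a1 <- assign_conditions(b, K = 15, seed = 42)
  a2 <- assign_conditions(b, K = 15, seed = 42)
  expect_identical(a1$label, a2$label)
  expect_error(assign_conditions(b, K = 5000, seed = 1), "SH1")
  # degenerate: equal class medians shrink the SH2/SE2 interval to a point
  rt_hc <- rep(c(0.6, 0.8, 1.0, 1.2, 1.4), 4)
  rt_lc <- rep(c(0.5, 0.9, 1.0, 1.1, 1.5), 4)
  beh <- data.frame(trial_id = 1:40, g = rep(c(0.45, 0), each = 20),
                    rt_s = c(rt_hc, rt_lc))
  expect_error(assign_conditions(beh, high_g_set = 0.45, low_g_set = 0, K = 5),
               "SH2|SE2")
})

test_that("RT summary reports medians, differences and the rank test", {
  beh <- data.frame(trial_id = 1:10, g = rep(c(0.45, 0), 5),
                    rt_s = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                    complexity = rep(c("HC", "LC"), 5))
  s <- summarize_rts(beh)
  expect_equal(s$difference, 0)
  # hand table: median is the sorted middle element
  beh2 <- data.frame(trial_id = 1:10, g = c(rep(0.45, 5), rep(0, 5)),
                     rt_s = c(5, 1, 4, 2, 3, rep(1, 5)))
  expect_equal(summarize_rts(beh2)$class_medians[["HC"]], 3)
  b <- simulate_rts(behavioral_model(training_drift = 0), 10000, seed = 12)
  expect_equal(summarize_rts(b)$difference, 0.3, tolerance = 0.05 / 0.3)
  expect_error(summarize_rts(data.frame(trial_id = 1, g = 0.5, rt_s = 1,
                                        complexity = "HC")), "empty")
})
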