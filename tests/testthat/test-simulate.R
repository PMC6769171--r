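test_that("simulated RT medians converge to the configured class medians", {
  b <- simulate_rts(behavioral_model(training_drift = 0), 10000, seed = 11)
  expect_equal(median(b$rt_s[b$complexity == "HC"]), 1.1, tolerance = 0.03 / 1.1)
  expect_equal(median(b$rt_s[b$complexity == "LC"]), 0.8, tolerance = 0.03 / 0.8)
})

test_that("zero dispersion gives RTs exactly at the drifted class median", {
  m <- behavioral_model(dispersion = 0, training_drift = 0.4)
  b <- simulate_rts(m, 500, seed = 2)
  u <- (b$onset_s - b$onset_s[1]) / (b$onset_s[500] - b$onset_s[1])
  hc <- b$complexity == "HC"
  expect_equal(b$rt_s[hc], 1.1 * (1 + 0.4 * (0.5 - u[hc])))
  expect_equal(b$rt_s[!hc], rep(0.8, sum(!hc)))
})

test_that("training drift makes early HC deciles slower than late ones", {
  b <- simulate_rts(behavioral_model(training_drift = 0.4), 5000, seed = 3)
  hc <- b[b$complexity == "HC", ]
  hc <- hc[order(hc$onset_s), ]
  dec <- floor(nrow(hc) / 10)
  # brute-force sort-and-median oracle per decile
  first <- median(sort(hc$rt_s[1:dec]))
  last <- median(sort(hc$rt_s[(nrow(hc) - dec + 1):nrow(hc)]))
  expect_gt(first, last)
})

test_that("behavioral model rejects invalid parameters", {
  expect_error(behavioral_model(median_rt_hc = 0.5, median_rt_lc = 0.8),
               "median_rt_hc > median_rt_lc")
  expect_error(behavioral_model(median_rt_lc = -1), "median_rt")
  expect_error(simulate_rts(behavioral_model(), 0), "positive")
})

test_that("presentation and inter-stimulus timings respect their ranges", {
  b <- simulate_rts(behavioral_model(), 2000, seed = 4)
  expect_true(all(b$presentation_s >= 1 & b$presentation_s <= 1.5))
  gaps <- diff(b$onset_s) - b$presentation_s[-nrow(b)]
  expect_true(all(gaps >= 3 - 1e-9 & gaps <= 5 + 1e-9))
})

test_that("coupling_spec enforces its invariants", {
  ok <- data.frame(source = 1, target = 2, lag = 5, gain = 0.5,
                   polarity = "increasing")
  expect_s3_class(coupling_spec(ok), "coupling_spec")
  bad <- ok; bad$target <- 1
  expect_error(coupling_spec(bad), "self-coupling")
  bad <- ok; bad$lag <- 0
  expect_error(coupling_spec(bad), "lag")
  bad <- ok; bad$gain <- 1.5
  expect_error(coupling_spec(bad), "gain")
  expect_error(coupling_spec(ok, onset_time = 3), "onset_time")
})

test_that("envelopes are non-negative and seed-deterministic", {
  e1 <- simulate_envelope(300, 25, seed = 5)
  e2 <- simulate_envelope(300, 25, seed = 5)
  expect_identical(e1, e2)
  expect_true(all(e1 >= 0))
  expect_error(simulate_envelope(100, 6, cutoff = 4), "Nyquist")
})

test_that("trial simulation is bit-identical under a fixed seed", {
  spec <- coupling_spec(data.frame(source = 1, target = 2, lag = 5, gain = 1,
                                   polarity = "increasing"))
  a <- simulate_eeg_trials(spec, n_channels = 3, n_trials = 2, seed = 9)
  b <- simulate_eeg_trials(spec, n_channels = 3, n_trials = 2, seed = 9)
  expect_identical(a$data, b$data)
  expect_identical(a$envelopes, b$envelopes)
})

test_that("trial geometry matches the 4-s, 1-s-baseline layout", {
  spec <- coupling_spec(data.frame(source = 1, target = 2, lag = 5, gain = 1,
                                   polarity = "increasing"))
  tr <- simulate_eeg_trials(spec, n_channels = 31, fs = 250, n_trials = 20,
                            snr = 5, seed = 1)
  expect_equal(dim(tr$data), c(31, 1000, 20))
  expect_equal(tr$onset_index, 250)
  expect_equal(tr$channel_labels, default_montage())
})

test_that("a gain-1 noiseless link copies the lagged source envelope exactly", {
  spec <- coupling_spec(data.frame(source = 1, target = 2, lag = 5, gain = 1,
                                   polarity = "increasing"),
                        onset_time = 0.5, band = "beta")
  tr <- simulate_eeg_trials(spec, n_channels = 3, fs = 250, n_trials = 2,
                            snr = Inf, seed = 7)
  post <- (250 + 125 + 1):1000           # after the 0.5-s switch
  for (k in 1:2)
    expect_equal(tr$envelopes$beta[post, 2, k],
                 tr$envelopes$beta[post - 5, 1, k])
  # alpha band untouched by a beta-band spec
  expect_false(isTRUE(all.equal(tr$envelopes$alpha[post, 2, 1],
                                tr$envelopes$alpha[post - 5, 1, 1])))
})

test_that("out-of-range channels in a coupling spec are rejected", {
  spec <- coupling_spec(data.frame(source = 1, target = 9, lag = 5, gain = 1,
                                   polarity = "increasing"))
  expect_error(simulate_eeg_trials(spec, n_channels = 4, n_trials = 1),
               "outside")
})

test_that("planted couplings are recoverable by an exhaustive lag scan", {
  hits <- 0
  runs <- 40
  for (s in seq_len(runs)) {
    e <- simulate_coupled_envelopes(400, lag = 5, gain = 0.8, snr = 3,
                                    fs = 25, seed = 300 + s)
    cc <- vapply(1:12, function(L)
      cor(e$x[1:(400 - L)], e$y[(1 + L):400]), numeric(1))
    hits <- hits + (which.max(cc) == 5)
  }
  expect_gte(hits / runs, 0.95)
})

test_that("frontal-hub preset concentrates sources in F and Fp", {
  spec <- preset_frontal_hub_spec()
  expect_s3_class(spec, "coupling_spec")
  labels <- default_montage()
  map <- default_region_map()
  frontal <- match(c(map$F, map$Fp), labels)
  inc <- spec$links[spec$links$polarity == "increasing", ]
  expect_true(all(inc$source %in% frontal))
  expect_equal(nrow(inc), 2 * length(frontal))
  # brute-force out-degree count over the link list: hubs beat non-frontal
  outdeg <- table(factor(inc$source, levels = 1:31))
  expect_gt(min(outdeg[frontal]), max(outdeg[-frontal]))
  expect_error(preset_frontal_hub_spec(region_map = list(O = "O1")),
               "F")
})
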