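test_that("recurrence matrices match the brute-force construction", {
  # fixed-threshold hand example
  Rm <- recurrence_matrix(c(0, 1, 0, 2, 0, 3), epsilon = 0.5)
  expect_equal(unclass(Rm)[1, 3], 1L, ignore_attr = TRUE)
  expect_equal(unname(Rm[cbind(c(1, 1, 3), c(3, 5, 5))]), rep(1L, 3))
  expect_equal(unname(Rm[1, 2]), 0L)
  for (s in 1:40) {
    set.seed(s)
    n <- sample(10:60, 1)
    E <- runif(n)
    Rm <- recurrence_matrix(E, target_rr = 0.3)
    expect_equal(unclass(Rm), bf_recurrence(E, attr(Rm, "epsilon")),
                 ignore_attr = TRUE)
    expect_true(all(diag(Rm) == 1))
    expect_equal(unclass(Rm), t(unclass(Rm)), ignore_attr = TRUE)
  }
})

test_that("the fixed-rate threshold achieves the target recurrence rate", {
  for (s in 1:10) {
    set.seed(s)
    E <- rnorm(50)
    Rm <- recurrence_matrix(E, target_rr = 0.2)
    m <- 50 * 49 / 2
    # achieved recurrent-pair count within a pair of the target count
    expect_lte(abs(attr(Rm, "recurrence_rate") * m - 0.2 * m), 1.5)
  }
})

test_that("a constant series yields an all-ones matrix with a warning", {
  expect_warning(Rm <- recurrence_matrix(rep(2, 12), target_rr = 0.1),
                 "degenerate")
  expect_true(all(Rm == 1))
})

test_that("joint recurrence is the elementwise product", {
  set.seed(7)
  for (s in 1:20) {
    Rx <- matrix(rbinom(2500, 1, 0.3), 50, 50)
    Ry <- matrix(rbinom(2500, 1, 0.3), 50, 50)
    expect_equal(joint_recurrence(Rx, Ry), bf_joint(Rx, Ry),
                 ignore_attr = TRUE)
  }
  R <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_equal(joint_recurrence(R, R), R)
  expect_equal(joint_recurrence(R, matrix(1, 10, 10)), R)
  expect_error(joint_recurrence(R, matrix(1, 9, 9)), "shape")
})

test_that("the N = 4 identity-recurrence construction gives RMD = 2 exactly", {
  I4 <- diag(4)
  expect_identical(rmd_from_matrices(I4, I4), 2)
})

test_that("self-dependence is never negative", {
  for (s in 1:20) {
    set.seed(s)
    x <- runif(sample(20:100, 1))
    expect_gte(rmd_value(x, x), 0)
  }
})

test_that("independence bias matches its finite-size prediction and decays", {
  # for iid series at rate rr, the unit diagonal inflates RMD by about
  # log2(1 + 1/(N rr^2)); the measure approaches 0 as N or rr grow
  rr <- 0.3
  bias_at <- function(n, seeds = 30) {
    mean(vapply(seeds * 100 + seq_len(seeds), function(s) {
      set.seed(s)
      rmd_value(runif(n), runif(n), target_rr = rr)
    }, numeric(1)))
  }
  b200 <- bias_at(200)
  b600 <- bias_at(600)
  expect_equal(b200, log2(1 + 1 / (200 * rr^2)), tolerance = 0.5)
  expect_gt(b200, b600)
  expect_lt(b600, 0.05)
})

test_that("rmd_value matches the brute-force density evaluation", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(12:60, 1)
    x <- runif(n); y <- runif(n)
    Rx <- recurrence_matrix(x, 0.3)
    Ry <- recurrence_matrix(y, 0.3)
    expect_equal(rmd_value(x, y, 0.3), bf_rmd(unclass(Rx), unclass(Ry)))
  }
  expect_error(rmd_value(runif(5), runif(5)), "short")
  expect_error(rmd_value(runif(20), runif(19)), "equal length")
})

test_that("compiled and reference lag scans agree", {
  for (s in 1:10) {
    set.seed(s)
    x <- runif(60); y <- runif(60)
    pc <- rmd_lagged(x, y, tau_max = 8, engine = "cpp")
    pr <- rmd_lagged(x, y, tau_max = 8, engine = "r")
    expect_equal(pc$rmd, pr$rmd, tolerance = 1e-12)
    expect_identical(pc$tau_star, pr$tau_star)
  }
})

test_that("lag zero is never evaluated and the grid is symmetric", {
  p <- rmd_lagged(runif(50), runif(50), tau_max = 6)
  expect_false(0 %in% p$lags)
  expect_setequal(p$lags, c(-(1:6), 1:6))
  expect_error(rmd_lagged(runif(15), runif(15), tau_max = 10), "short")
  expect_error(rmd_lagged(runif(50), runif(50), tau_max = 0), "tau_max")
})

test_that("the lag profile is antisymmetric under argument exchange", {
  set.seed(11)
  x <- runif(60); y <- runif(60)
  pxy <- rmd_lagged(x, y, tau_max = 5)
  pyx <- rmd_lagged(y, x, tau_max = 5)
  expect_equal(pxy$rmd, rev(pyx$rmd), tolerance = 1e-12)
})

test_that("a planted delay is recovered with the right direction", {
  e <- simulate_coupled_envelopes(300, lag = 5, gain = 1, snr = Inf, seed = 3)
  p <- rmd_lagged(e$x, e$y, tau_max = 10)
  expect_identical(p$tau_star, 5L)
  back <- rmd_lagged(e$y, e$x, tau_max = 10)
  expect_identical(back$tau_star, -5L)
})

test_that("RMD* is non-decreasing in coupling gain", {
  mean_star <- function(gain) {
    mean(vapply(1:50, function(s) {
      e <- simulate_coupled_envelopes(300, lag = 4, gain = max(gain, 1e-9),
                                      snr = 3, fs = 25, seed = 800 + s)
      if (gain == 0) {
        ey <- simulate_envelope(300, 25, seed = 4000 + s)
        rmd_lagged(e$x, ey, tau_max = 8)$rmd_star
      } else {
        rmd_lagged(e$x, e$y, tau_max = 8)$rmd_star
      }
    }, numeric(1)))
  }
  stars <- c(mean_star(0), mean_star(0.5), mean_star(1))
  expect_true(all(diff(stars) > 0))
})

test_that("link_samples does per-window bookkeeping over trials", {
  tr <- planted_pair_trials(n_trials = 4, onset_time = 0.5, seed = 13)
  bp <- extract_band_envelopes(tr, "beta")
  ls <- link_samples(bp, pair = c(1, 2))
  expect_length(ls$baseline, 4)
  expect_equal(dim(ls$task), c(4, 21))
  expect_equal(ls$window_centers, seq(0.5, 2.5, by = 0.1))
  # a task window at the baseline location reproduces the baseline values
  ls2 <- link_samples(bp, pair = c(1, 2), windows = matrix(c(-1, 0), 1))
  expect_equal(ls2$task[, 1], ls2$baseline)
  expect_error(link_samples(bp, pair = c(1, 2),
                            windows = matrix(c(2.5, 3.5), 1)), "bounds")
})

test_that("post-onset windows show elevated RMD for a planted coupling", {
  wins <- 0
  runs <- 15
  for (s in seq_len(runs)) {
    tr <- planted_pair_trials(n_trials = 10, onset_time = 0.5, seed = 900 + s)
    bp <- extract_band_envelopes(tr, "beta")
    ls <- link_samples(bp, pair = c(1, 2),
                       windows = cbind(start = c(1, 1.5), end = c(2, 2.5)))
    wins <- wins + (mean(ls$task) > mean(ls$baseline))
  }
  expect_gte(wins / runs, 0.9)
})
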