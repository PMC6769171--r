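test_that("the link ratio handles counts and sentinels", {
  M <- function(k, n = 5) {
    m <- matrix(0L, n, n)
    if (k > 0) m[cbind(seq_len(k), seq_len(k) %% n + 1)] <- 1L
    m
  }
  expect_equal(link_ratio(M(2), M(2)), 1)
  expect_equal(link_ratio(M(3), M(1)), 3)
  expect_identical(link_ratio(M(2), M(0)), Inf)
  expect_true(is.nan(link_ratio(M(0), M(0))))
  # scale-free: duplicating every link leaves R unchanged
  expect_equal(link_ratio(M(4), M(2)), 2)
  expect_equal(link_ratio(rbind(cbind(M(4), M(0)), cbind(M(0), M(4))),
                          rbind(cbind(M(2), M(0)), cbind(M(0), M(2)))), 2)
})

test_that("out-degree equals the brute-force row count", {
  z <- matrix(0L, 6, 6)
  expect_equal(unname(out_degree(z)), rep(0, 6))
  m <- z; m[2, c(1, 3, 5, 6)] <- 1L
  expect_equal(unname(out_degree(m)[2]), 4)
  for (s in 1:20) {
    set.seed(s)
    M <- matrix(rbinom(100, 1, 0.3), 10, 10); diag(M) <- 0L
    expect_equal(unname(out_degree(M)), bf_out_degree(M))
  }
  expect_error(out_degree(matrix(2, 3, 3)), "binary")
  expect_error(out_degree(matrix(0, 2, 3)), "square")
})

test_that("region degrees are per-region means of channel degrees", {
  map <- default_region_map()
  labels <- default_montage()
  D <- setNames(rep(3, 31), labels)
  expect_true(all(region_degree(D, map) == 3))
  D2 <- setNames(rep(0, 31), labels)
  D2[map$O] <- c(1, 2, 3)
  expect_equal(unname(region_degree(D2, map)["O"]), 2)
  for (s in 1:20) {
    set.seed(s)
    Dr <- setNames(rpois(31, 2), labels)
    rd <- region_degree(Dr, map)
    for (rg in names(map))
      expect_equal(unname(rd[rg]), bf_region_mean(as.list(Dr), map[[rg]]))
  }
  expect_error(region_degree(D, c(map, list(X = character()))), "empty")
})

test_that("the timeline instants follow the crossing and maximum rules", {
  tl <- extract_timeline(c(0.5, 0.8, 1.2, 1.5, 2.0, 1.8),
                         seq(0.1, 0.6, by = 0.1))
  expect_equal(tl$t1, 0.3)
  expect_equal(tl$t3, 0.5)
  expect_equal(tl$t2, 0.4)
  # never crossing
  tl2 <- extract_timeline(rep(0.7, 5), 1:5 / 10)
  expect_true(is.na(tl2$t1) && is.na(tl2$t2) && is.na(tl2$t3))
  # a single isolated crossing is debounced away
  tl3 <- extract_timeline(c(0.5, 1.1, 0.5, 0.6, 0.7), 1:5 / 10)
  expect_true(is.na(tl3$t1))
  # infinity sentinels count as R > 1; NaN never does
  tl4 <- extract_timeline(c(NaN, Inf, Inf, 2), 1:4 / 10)
  expect_equal(tl4$t1, 0.2)
  expect_equal(tl4$t3, 0.2)                  # earliest max on ties
  expect_error(extract_timeline(c(1, 2), c(0.1, 0.2)), "3 windows")
})

test_that("appending sub-unity windows after t3 changes nothing", {
  R <- c(0.5, 1.2, 1.4, 2.0, 1.1)
  tms <- 1:5 / 10
  a <- extract_timeline(R, tms)
  b <- extract_timeline(c(R, 0.4, 0.2), c(tms, 0.6, 0.7))
  expect_equal(a[c("t1", "t2", "t3")], b[c("t1", "t2", "t3")])
})

test_that("network_timeline assembles degrees and instants per window", {
  labels <- default_montage()
  mk <- function(k_inc, k_dec) {
    inc <- matrix(0L, 31, 31, dimnames = list(labels, labels))
    dec <- inc
    if (k_inc > 0) inc[24, seq_len(k_inc)] <- 1L        # F7 drives posteriors
    if (k_dec > 0) dec[1, 3 + seq_len(k_dec)] <- 1L
    structure(list(M_inc = inc, M_dec = dec,
                   flagged = data.frame()), class = "link_networks")
  }
  nets <- list(mk(0, 2), mk(2, 2), mk(4, 2), mk(6, 2))
  tl <- network_timeline(nets, c(0.5, 0.6, 0.7, 0.8), band = "beta")
  expect_equal(tl$R, c(0, 1, 2, 3))
  expect_equal(tl$t1, 0.7)
  expect_equal(tl$t3, 0.8)
  expect_equal(unname(tl$D["F7", 4]), 6)
  expect_equal(unname(tl$region_D["F", 4]), 6 / 5)
})

test_that("the timeline report computes RT lags and warns on gaps", {
  mk_tl <- function(band, cond, t1) {
    structure(list(times = 1:3 / 10, R = c(1, 2, 3), D = NULL, region_D = NULL,
                   t1 = t1, t2 = t1 + 0.1, t3 = t1 + 0.2,
                   band = band, condition = cond), class = "network_timeline")
  }
  tls <- list(mk_tl("beta", "SH1", 0.8), mk_tl("alpha", "SH1", 1.0))
  rep1 <- timeline_vs_rt_report(tls, c(SH1 = 1.2))
  expect_equal(rep1$rt_minus_t1_beta, 0.4)
  expect_equal(rep1$t1_alpha, 1.0)
  expect_warning(timeline_vs_rt_report(tls, c(SH1 = 1.2, SE2 = 0.9)),
                 "SE2")
})
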