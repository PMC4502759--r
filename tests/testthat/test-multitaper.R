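test_that("dpss tapers are orthonormal, correctly counted, and concentrated", {
  tp <- dpss_tapers(512, 2, 3)
  expect_equal(dim(tp), c(3, 512))
  expect_equal(tp %*% t(tp), diag(3), tolerance = 1e-10)
  expect_error(dpss_tapers(512, 2, 4), "2\\*TW - 1")
  # concentration oracle: quadratic form with the sinc kernel for W = TW/n
  n <- 512
  w <- 2 / n
  d <- outer(0:(n - 1), 0:(n - 1), `-`)
  A <- ifelse(d == 0, 2 * w, sin(2 * pi * w * d) / (pi * d))
  conc <- vapply(1:3, function(k) drop(tp[k, ] %*% A %*% tp[k, ]),
                 numeric(1))
  expect_gt(conc[1], 0.99)
  expect_true(all(diff(conc) < 0))  # decreasing concentration order
})

test_that("spectrogram resolves a sinusoid and counts windows correctly", {
  fs <- 256
  x <- sin(2 * pi * 10 * (0:(300 * fs - 1)) / fs)
  sp <- multitaper_spectrogram(x, multitaper_params(fs = fs))
  expect_equal(length(sp$times), floor((300 - 2) / 0.1) + 1)  # 2981
  expect_equal(length(sp$times), 2981)
  ms <- colMeans(10^(sp$power / 10))
  expect_equal(sp$freqs[which.max(ms)], 10)
  expect_gt(sum(ms[abs(sp$freqs - 10) <= 0.5]) / ms[sp$freqs == 20], 100)
})

test_that("an all-zero epoch gives -Inf dB power", {
  sp <- multitaper_spectrogram(rep(0, 1024), multitaper_params(fs = 256))
  expect_true(all(sp$power == -Inf))
})

test_that("an epoch shorter than one window is rejected", {
  expect_error(multitaper_spectrogram(rnorm(100),
                                      multitaper_params(fs = 256)),
               "shorter")
})

test_that("multitaper power satisfies a Parseval check on white noise", {
  set.seed(7)
  fs <- 256
  x <- rnorm(20 * fs)
  sp <- multitaper_spectrogram(x, multitaper_params(fs = fs))
  df <- diff(sp$freqs)[1]
  total <- mean(rowSums(10^(sp$power / 10))) * df
  expect_equal(total / stats::var(x), 1, tolerance = 0.05)
  expect_true(all(is.finite(sp$power)))  # power > 0 everywhere
})

test_that("estimator variance grows as K decreases on white noise", {
  set.seed(42)
  fs <- 256
  vr <- function(K) {
    v <- replicate(60, {
      x <- rnorm(2 * fs)
      sp <- multitaper_spectrogram(x, multitaper_params(
        overlap = 0, TW = 2, K = K, fs = fs))
      sp$power[1, 21]
    })
    stats::var(v)
  }
  expect_gt(vr(1), vr(3))
})

test_that("group-median spectrogram equals the sort-based oracle", {
  freqs <- seq(0, 30, by = 0.5)
  ests <- lapply(1:19, function(i) {
    fake_estimate(matrix(rnorm(5 * length(freqs)), nrow = 5), freqs)
  })
  gm <- group_median_spectrogram(ests)
  oracle <- apply(
    vapply(ests, function(e) e$power, ests[[1]]$power), c(1, 2),
    function(v) sort(v)[c(10)])  # n=19: middle order statistic
  expect_equal(gm$power, oracle)
  expect_equal(gm$n_subjects, 19)
  # single subject: identity; constant bins: plain median
  expect_equal(group_median_spectrogram(ests[1])$power, ests[[1]]$power)
  consts <- lapply(c(1, 2, 9), function(v) {
    fake_estimate(matrix(v, 2, length(freqs)), freqs)
  })
  expect_true(all(group_median_spectrogram(consts)$power == 2))
})

test_that("group median is invariant to subject order", {
  freqs <- seq(0, 30, by = 0.5)
  ests <- lapply(1:7, function(i) {
    fake_estimate(matrix(rnorm(3 * length(freqs)), nrow = 3), freqs)
  })
  a <- group_median_spectrogram(ests)
  b <- group_median_spectrogram(rev(ests))
  expect_equal(a$power, b$power)
})

test_that("mismatched grids are rejected", {
  e1 <- fake_estimate(matrix(0, 2, 5), freqs = 1:5)
  e2 <- fake_estimate(matrix(0, 2, 5), freqs = 2:6)
  expect_error(group_median_spectrogram(list(e1, e2)), "common")
})

test_that("group spectrum matches a brute-force percentile oracle", {
  freqs <- seq(0, 30, by = 0.5)
  set.seed(3)
  ests <- lapply(1:11, function(i) {
    fake_estimate(matrix(10 * log10(rexp(4 * length(freqs))), nrow = 4),
                  freqs)
  })
  ps <- group_spectrum(ests, group = "young")
  means_db <- vapply(ests, function(e) {
    10 * log10(colMeans(10^(e$power / 10)))
  }, numeric(length(freqs)))
  for (j in c(1, 20, 61)) {
    q <- stats::quantile(means_db[j, ], c(0.25, 0.5, 0.75), type = 7)
    expect_equal(ps$p25_db[j], unname(q[1]))
    expect_equal(ps$median_db[j], unname(q[2]))
    expect_equal(ps$p75_db[j], unname(q[3]))
  }
  expect_true(all(ps$p25_db <= ps$median_db & ps$median_db <= ps$p75_db))
  # single stationary subject: median equals the time-mean, zero-width IQR
  one <- group_spectrum(ests[1])
  expect_equal(one$median_db, means_db[, 1])
  expect_equal(one$p25_db, one$p75_db)
})

test_that("band topography recovers a flat spectrum within 1 dB", {
  freqs <- seq(0, 30, by = 0.5)
  set.seed(9)
  ests <- stats::setNames(lapply(1:5, function(i) {
    # white-ish noise around 0 dB
    fake_estimate(matrix(rnorm(40 * length(freqs), sd = 1), nrow = 40),
                  freqs)
  }), c("F7", "F8", "Cz", "O1", "O2"))
  tp <- band_power_topography(ests)
  vals <- unlist(tp[, band_scheme()$band])
  expect_lt(max(vals) - min(vals), 1)
  expect_equal(tp$electrode, names(ests))
})

test_that("a band with no grid bins is rejected and NA electrodes pass through", {
  coarse <- fake_estimate(matrix(0, 3, 16), freqs = seq(0, 30, by = 2))
  expect_error(band_power_topography(list(F7 = coarse)), "slow")
  fine <- fake_estimate(matrix(0, 3, 61), freqs = seq(0, 30, by = 0.5))
  tp <- band_power_topography(list(F7 = fine, F8 = NULL))
  expect_true(all(is.na(unlist(tp[tp$electrode == "F8",
                                  band_scheme()$band]))))
})

test_that("invalid multitaper parameter combinations are rejected", {
  expect_error(multitaper_params(K = 4, TW = 2), "2\\*TW - 1")
  expect_error(multitaper_params(overlap = 2, window_T = 2), "overlap")
  expect_error(multitaper_params(K = 0), "K")
})
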