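test_that("replicates are seeded, unbiased, and Gamma-distributed", {
  freqs <- seq(0.5, 30, 0.5)
  s <- fake_spectrum(freqs, rep(4, length(freqs)), m = 30)
  r1 <- resample_subject_spectrum(s, seed = 7)
  r2 <- resample_subject_spectrum(s, seed = 7)
  expect_identical(r1$power, r2$power)
  # zero power stays zero; negative power rejected
  s0 <- fake_spectrum(freqs, rep(0, length(freqs)), m = 30)
  expect_true(all(resample_subject_spectrum(s0, seed = 1)$power == 0))
  sneg <- fake_spectrum(freqs, c(-1, rep(1, length(freqs) - 1)))
  expect_error(resample_subject_spectrum(sneg, seed = 1), "non-negative")
  # distribution oracle: mean of m squared complex-normal coefficients is
  # Gamma(shape = m, scale = S/m); KS test over 5000 draws
  one <- fake_spectrum(1, 4, m = 30)
  draws <- withr::with_seed(11, {
    replicate(5000, resample_subject_spectrum(one)$power)
  })
  ks <- stats::ks.test(draws, stats::pgamma, shape = 30, rate = 30 / 4)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(draws), 4, tolerance = 0.02)
})

test_that("unbiasedness holds across a spectrum at m = 30", {
  freqs <- seq(0.5, 30, 0.5)
  Strue <- 10 * exp(-freqs / 8) + 0.5
  s <- fake_spectrum(freqs, Strue, m = 30)
  acc <- withr::with_seed(13, {
    Reduce(`+`, lapply(1:2000, function(i) {
      resample_subject_spectrum(s)$power
    }))
  }) / 2000
  expect_true(all(abs(acc / Strue - 1) < 0.02))
})

test_that("identical groups give zero observed difference and ~5% hits", {
  freqs <- seq(0.5, 30, 0.5)
  set.seed(17)
  A <- lapply(1:8, function(i) {
    fake_spectrum(freqs, 5 * stats::rgamma(length(freqs), 100, 100),
                  m = 100)
  })
  bt <- bootstrap_group_difference(A, A, bootstrap_config(
    n_replicates = 400, seed = 5))
  expect_true(all(bt$observed_db == 0))
  # copies of the same group: few (conservatively <= ~5%) significant bins
  expect_lt(mean(bt$significant), 0.05 + 0.075)
})

test_that("degenerate spectra with huge m give vanishing CI width", {
  freqs <- seq(1, 10, 1)
  A <- lapply(1:5, function(i) fake_spectrum(freqs, rep(3, 10), m = 1e6))
  B <- lapply(1:5, function(i) fake_spectrum(freqs, rep(3, 10), m = 1e6))
  bt <- bootstrap_group_difference(A, B, bootstrap_config(
    n_replicates = 200, seed = 2))
  expect_lt(max(bt$upper_db - bt$lower_db), 0.1)
})

test_that("an injected alpha offset is detected in the alpha band", {
  freqs <- seq(0.5, 30, 0.5)
  alpha <- freqs > 8 & freqs <= 12
  set.seed(19)
  mk <- function(offset_db) {
    S <- rep(5, length(freqs))
    S[alpha] <- S[alpha] * 10^(offset_db / 10)
    lapply(1:10, function(i) {
      fake_spectrum(freqs, S * stats::rgamma(length(freqs), 100, 100),
                    m = 100)
    })
  }
  bt <- bootstrap_group_difference(mk(6), mk(0), bootstrap_config(
    n_replicates = 500, seed = 23))
  bs <- band_significance(bt)
  expect_gt(bs$frac_significant[bs$band == "alpha"], 0.9)
  others <- bs$frac_significant[bs$band %in% c("delta", "theta", "beta")]
  expect_true(all(others < 0.3))
  # monotone power in the injected offset
  fracs <- vapply(c(0, 2, 4, 6), function(off) {
    b <- bootstrap_group_difference(mk(off), mk(0), bootstrap_config(
      n_replicates = 300, seed = 29))
    mean(b$significant[alpha])
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
  expect_lt(fracs[1], 0.3)
  expect_gt(fracs[4], 0.9)
})

test_that("paired comparisons require matched lists and detect shifts", {
  freqs <- seq(0.5, 30, 0.5)
  set.seed(31)
  A <- lapply(1:6, function(i) {
    fake_spectrum(freqs, 5 * stats::rgamma(length(freqs), 100, 100),
                  m = 100)
  })
  expect_error(bootstrap_group_difference(
    A, A[1:3], bootstrap_config(paired = TRUE)), "equal-length")
  B <- lapply(A, function(s) fake_spectrum(freqs, s$power * 2, m = 100))
  bt <- bootstrap_group_difference(B, A, bootstrap_config(
    n_replicates = 300, paired = TRUE, seed = 3))
  expect_equal(bt$observed_db, rep(10 * log10(2), length(freqs)))
  expect_gt(mean(bt$significant), 0.95)
})

test_that("bootstrap results reproduce exactly from the config seed", {
  freqs <- seq(0.5, 30, 0.5)
  set.seed(37)
  A <- lapply(1:5, function(i) {
    fake_spectrum(freqs, stats::rgamma(length(freqs), 50, 10), m = 50)
  })
  B <- lapply(1:5, function(i) {
    fake_spectrum(freqs, stats::rgamma(length(freqs), 50, 10), m = 50)
  })
  cfg <- bootstrap_config(n_replicates = 200, seed = 41)
  expect_identical(bootstrap_group_difference(A, B, cfg),
                   bootstrap_group_difference(A, B, cfg))
})

test_that("MOSSA-vs-movement comparison drops incomplete subjects", {
  pre1 <- quick_preprocessed("P1", seed = 51)
  eps1 <- extract_state_epochs(pre1$rec, pre1$sevo, pre1$movement,
                               state = "first_movement")
  st1 <- vapply(eps1, function(e) e$state, "")
  pair1 <- list(mossa = eps1[[which(st1 == "MOSSA")]],
                movement = eps1[[which(st1 == "first_movement")]])
  pairs <- list(pair1, pair1, list(mossa = NULL, movement = NULL))
  expect_message(
    bt <- mossa_vs_movement_difference(
      pairs, bootstrap_config(n_replicates = 150, seed = 1)),
    "dropping")
  expect_equal(attr(bt, "n_A"), 2)
  expect_error(
    suppressMessages(mossa_vs_movement_difference(
      list(list(mossa = NULL, movement = NULL)),
      bootstrap_config(n_replicates = 150, seed = 1))),
    "no subjects")
})

test_that("bootstrap config validation rejects inconsistent settings", {
  expect_error(bootstrap_config(n_replicates = 10), "at least 100")
  expect_error(bootstrap_config(ci_level = 0), "ci_level")
  expect_error(bootstrap_config(ci_level = 100), "ci_level")
})
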