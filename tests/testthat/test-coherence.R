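test_that("self-coherence and sign-flipped coherence equal one", {
  set.seed(1)
  x <- rnorm(60 * 256)
  ep <- matrix_epoch(cbind(a = x, b = x))
  cg <- pairwise_coherogram(ep, "a", "b")
  expect_true(all(abs(cg$coherence - 1) < 1e-12))
  ep$data[, "b"] <- -x
  cg2 <- pairwise_coherogram(ep, "a", "b")
  expect_true(all(abs(cg2$coherence - 1) < 1e-12))
})

test_that("coherence lies in [0, 1] and zero spectra are flagged NA", {
  set.seed(2)
  ep <- matrix_epoch(cbind(a = rnorm(20 * 256), b = rnorm(20 * 256)))
  cg <- pairwise_coherogram(ep, "a", "b")
  expect_true(all(cg$coherence >= 0 & cg$coherence <= 1, na.rm = TRUE))
  ep0 <- matrix_epoch(cbind(a = rep(0, 512), b = rnorm(512)))
  cg0 <- pairwise_coherogram(ep0, "a", "b")
  expect_true(all(is.na(cg0$coherence)))
  expect_error(pairwise_coherogram(ep, "a", "zz"), "not found")
})

test_that("independent-channel coherence matches the K=5 null oracle", {
  # Monte-Carlo oracle of the single-window K-taper estimator's null
  # distribution: coherence of two independent complex Gaussian K-vectors
  set.seed(4)
  K <- 5
  null_med <- stats::median(replicate(4000, {
    xi <- complex(real = rnorm(K), imaginary = rnorm(K))
    xj <- complex(real = rnorm(K), imaginary = rnorm(K))
    Mod(sum(xi * Conj(xj))) / sqrt(sum(Mod(xi)^2) * sum(Mod(xj)^2))
  }))
  ep <- matrix_epoch(cbind(a = rnorm(300 * 256), b = rnorm(300 * 256)))
  cg <- pairwise_coherogram(ep, "a", "b")
  measured <- stats::median(cg$coherence)
  expect_equal(measured, null_med, tolerance = 0.03)
})

test_that("group-median coherogram equals the sort oracle", {
  grid <- list(freqs = seq(0, 30, 0.5), times = 1:6)
  mk <- function() {
    structure(list(freqs = grid$freqs, times = grid$times,
                   coherence = matrix(runif(6 * 61), nrow = 6),
                   params = coherence_params(), n_subjects = 1L),
              class = "coherogram")
  }
  set.seed(5)
  cs <- lapply(1:16, function(i) mk())
  gm <- group_median_coherogram(cs)
  oracle <- apply(vapply(cs, function(x) x$coherence,
                         cs[[1]]$coherence), c(1, 2),
                  function(v) mean(sort(v)[8:9]))
  expect_equal(gm$coherence, oracle)
  expect_equal(group_median_coherogram(cs[1])$coherence,
               cs[[1]]$coherence)
  consts <- lapply(c(0.2, 0.6, 0.8), function(v) {
    x <- mk(); x$coherence[] <- v; x
  })
  expect_true(all(group_median_coherogram(consts)$coherence == 0.6))
})

test_that("identical channels give a rank-1 cross-spectral matrix", {
  set.seed(6)
  s <- rnorm(30 * 256)
  X <- matrix(rep(s, 5), ncol = 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  cm <- cross_spectral_matrix(matrix_epoch(X))
  for (f in c(2, 11, 41)) {
    ev <- eigen(cm$S[f, , ], symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(ev[2]) / ev[1], 1e-8)
  }
})

test_that("cross-spectral matrices are Hermitian with real diagonals", {
  set.seed(7)
  X <- matrix(rnorm(25 * 256 * 4), ncol = 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  cm <- cross_spectral_matrix(matrix_epoch(X))
  for (f in seq(1, length(cm$freqs), by = 40)) {
    H <- cm$S[f, , ]
    expect_lt(max(Mod(H - Conj(t(H)))), 1e-10 * max(Mod(H)))
    expect_true(all(abs(Im(diag(H))) < 1e-12))
    expect_true(all(Re(diag(H)) >= 0))
  }
})

test_that("off-diagonal magnitudes shrink with more windows", {
  # with W independent windows the null cross-spectrum magnitude scales as
  # 1/sqrt(W-ish); verified via a Monte-Carlo contrast of 20 s vs 180 s
  set.seed(8)
  rel_off <- function(secs) {
    X <- matrix(rnorm(secs * 256 * 2), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
    cm <- cross_spectral_matrix(matrix_epoch(X))
    stats::median(Mod(cm$S[, 1, 2]) / sqrt(Re(cm$S[, 1, 1]) *
                                             Re(cm$S[, 2, 2])))
  }
  expect_gt(rel_off(20), rel_off(180))
})

test_that("epochs shorter than one median block are rejected", {
  X <- matrix(rnorm(15 * 256 * 2), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_error(cross_spectral_matrix(matrix_epoch(X)), "at least 10")
})

test_that("global coherence of equal-power independent channels is 1/N", {
  N <- 6
  S <- array(0i, dim = c(3, N, N))
  for (f in 1:3) S[f, , ] <- diag(N) + 0i
  csm <- structure(list(freqs = c(1, 2, 3), S = S,
                        channels = paste0("c", 1:N), n_windows = 10,
                        n_blocks = 1, params = coherence_params()),
                   class = "cross_spectral_matrix")
  gc_ <- global_coherence(csm)
  expect_equal(gc_$c_global, rep(1 / N, 3))
})

test_that("global coherence matches a power-iteration + trace oracle", {
  set.seed(9)
  N <- 31
  A <- matrix(complex(real = rnorm(N * 40), imaginary = rnorm(N * 40)),
              nrow = N)
  H <- A %*% Conj(t(A)) / 40  # Hermitian PSD
  S <- array(0i, dim = c(1, N, N)); S[1, , ] <- H
  csm <- structure(list(freqs = 1, S = S, channels = paste0("c", 1:N),
                        n_windows = 10, n_blocks = 1,
                        params = coherence_params()),
                   class = "cross_spectral_matrix")
  gc_ <- global_coherence(csm)
  # independent oracle: power iteration for lambda_max, trace for the sum
  v <- complex(real = rnorm(N), imaginary = rnorm(N))
  for (i in 1:500) {
    v <- H %*% v
    v <- v / sqrt(sum(Mod(v)^2))
  }
  lmax <- Re(Conj(t(v)) %*% H %*% v)[1]
  expect_equal(gc_$c_global[1], lmax / Re(sum(diag(H))), tolerance = 1e-10)
  # eigenvalue sum equals the trace
  expect_equal(sum(gc_$eigenvalues[1, ]), Re(sum(diag(H))),
               tolerance = 1e-10)
})

test_that("global coherence is invariant to permutation and rescaling", {
  set.seed(10)
  X <- matrix(rnorm(30 * 256 * 5), ncol = 5,
              dimnames = list(NULL, paste0("c", 1:5)))
  base <- global_coherence(cross_spectral_matrix(matrix_epoch(X)))
  perm <- global_coherence(cross_spectral_matrix(
    matrix_epoch(X[, c(3, 1, 5, 2, 4)])))
  expect_equal(base$c_global, perm$c_global, tolerance = 1e-10)
  scaled <- global_coherence(cross_spectral_matrix(
    matrix_epoch(X * 7.3)))
  expect_equal(base$c_global, scaled$c_global, tolerance = 1e-10)
})

test_that("genuinely indefinite matrices are rejected", {
  S <- array(0i, dim = c(1, 2, 2))
  S[1, , ] <- matrix(c(1, 2, 2, 1), 2, 2) + 0i  # eigenvalues 3, -1
  csm <- structure(list(freqs = 1, S = S, channels = c("a", "b"),
                        n_windows = 10, n_blocks = 1,
                        params = coherence_params()),
                   class = "cross_spectral_matrix")
  expect_error(global_coherence(csm), "positive semi-definite")
})

test_that("spatial coherence maps reflect the principal mode support", {
  # rank-1 source on two of four electrodes
  N <- 4
  u <- c(1, 1, 0, 0) / sqrt(2)
  H <- outer(u, u) + 0i
  S <- array(0i, dim = c(2, N, N))
  S[1, , ] <- H; S[2, , ] <- H
  csm <- structure(list(freqs = c(10, 10.5), S = S,
                        channels = c("F7", "F8", "O1", "O2"),
                        n_windows = 10, n_blocks = 1,
                        params = coherence_params()),
                   class = "cross_spectral_matrix")
  sm <- spatial_coherence_map(global_coherence(csm))
  expect_equal(sm$alpha[1:2], c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sm$alpha[3:4], c(0, 0), tolerance = 1e-12)
})

test_that("stronger shared sources raise F7-F8 coherence monotonically", {
  mon <- test_montage()
  prof <- stats::setNames(rep(0, 33), mon$positions$label)
  prof[c("F7", "F8")] <- 1
  med_coh <- vapply(c(0.3, 1, 3, 9, 27), function(gain) {
    per_seed <- vapply(1:3, function(seed) {
      osc <- oscillator_spec("alpha", 10, 2, gain, prof)
      sp <- quick_subject(seed = seed, noise_rms = 5,
                          oscillators = list(awake = osc, induction = osc,
                                             MOSSA = osc, emergence = osc))
      rec <- generate_subject_eeg(sp)
      ep <- matrix_epoch(rec$data[(110 * 256):(170 * 256 - 1),
                                  c("F7", "F8")])
      cg <- pairwise_coherogram(ep, "F7", "F8")
      stats::median(cg$coherence[, cg$freqs == 10])
    }, numeric(1))
    stats::median(per_seed)
  }, numeric(1))
  expect_true(all(diff(med_coh) > 0))
  expect_lt(med_coh[1], 0.7)
  expect_gt(med_coh[5], 0.9)
})
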