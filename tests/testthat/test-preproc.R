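make_recording <- function(X, fs = 256) {
  structure(list(data = X, fs = fs, channels = colnames(X),
                 subject_id = "R", age_group = NA, timeline = NULL,
                 t_start = 0),
            class = "eeg_recording")
}

test_that("laplacian maps uniform fields to zero and is linear", {
  mon <- test_montage()
  w <- build_laplacian_weights(mon)
  labs <- mon$positions$label
  n <- 512
  X <- matrix(rep(sin(1:n / 10), 33), ncol = 33,
              dimnames = list(NULL, labs))
  out <- apply_laplacian(make_recording(X), w)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-12)
  expect_length(out$channels, 31)
  # single-electrode signal: unchanged there, neighbors get -w * signal
  X2 <- matrix(0, n, 33, dimnames = list(NULL, labs))
  s <- cos(1:n / 5)
  X2[, "C3"] <- s
  out2 <- apply_laplacian(make_recording(X2), w)
  expect_equal(out2$data[, "C3"], s)
  for (nb in mon$adjacency[["C3"]]) {
    expect_equal(out2$data[, nb], -w[[nb]]["C3"] * s,
                 ignore_attr = TRUE)
  }
  far <- setdiff(montage_channels(mon),
                 c("C3", names(which(vapply(w, function(v)
                   "C3" %in% names(v), TRUE)))))
  expect_equal(max(abs(out2$data[, far])), 0)
})

test_that("laplacian equals the dense (I - W) matrix oracle", {
  mon <- test_montage()
  w <- build_laplacian_weights(mon)
  labs <- mon$positions$label
  set.seed(1)
  X <- matrix(rnorm(200 * 33), ncol = 33, dimnames = list(NULL, labs))
  out <- apply_laplacian(make_recording(X), w)
  W <- attr(w, "matrix")
  oracle <- X[, rownames(W)] %*% t(diag(31) - W)
  expect_equal(unname(out$data), unname(oracle), tolerance = 1e-12)
})

test_that("laplacian rejects a recording with missing channels", {
  mon <- test_montage()
  w <- build_laplacian_weights(mon)
  X <- matrix(0, 10, 2, dimnames = list(NULL, c("F7", "F8")))
  expect_error(apply_laplacian(make_recording(X), w), "Oz")
})

test_that("antialias downsampling preserves passband and kills stopband", {
  fs <- 1024
  t <- (0:(fs * 4 - 1)) / fs
  X <- cbind(a = sin(2 * pi * 10 * t), b = sin(2 * pi * 120 * t),
             c = rep(1, length(t)))
  out <- antialias_downsample(make_recording(X, fs))
  expect_equal(out$fs, 256)
  expect_equal(nrow(out$data), length(t) / 4)
  t2 <- (0:(nrow(out$data) - 1)) / 256
  ref <- sin(2 * pi * 10 * t2)
  mid <- 50:(length(t2) - 50)
  expect_equal(out$data[mid, "a"], ref[mid], tolerance = 0.01)
  expect_lt(sqrt(mean(out$data[mid, "b"]^2)) / sqrt(0.5), 0.01)
  expect_equal(out$data[, "c"], rep(1, nrow(out$data)), tolerance = 1e-9)
})

test_that("a 256 Hz input is filtered but not decimated", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  X <- cbind(a = sin(2 * pi * 10 * t))
  out <- antialias_downsample(make_recording(X, fs))
  expect_equal(nrow(out$data), length(t))
  mid <- 50:(length(t) - 50)
  expect_equal(out$data[mid, "a"], sin(2 * pi * 10 * t)[mid],
               tolerance = 0.01)
})

test_that("non-integer decimation factors are rejected", {
  X <- cbind(a = rnorm(1000))
  expect_error(antialias_downsample(make_recording(X, 300)),
               "integer multiple")
})

test_that("MOSSA extraction finds a 300-s epoch inside a stable plateau", {
  pre <- quick_preprocessed(seed = 31)
  eps <- extract_state_epochs(pre$rec, pre$sevo, state = "MOSSA")
  expect_length(eps, 1)
  ep <- eps[[1]]
  expect_equal(ep$duration, 300)
  expect_equal(ep$state, "MOSSA")
  expect_equal(ep$subject_id, "T01")
  # epoch lies wholly inside the plateau segment
  tl <- pre$spec$timeline
  expect_gte(ep$t_start, tl$t_start[3])
  expect_lte(ep$t_start + 300, tl$t_end[3])
  conc <- pre$sevo$concentration[pre$sevo$time >= ep$t_start &
                                   pre$sevo$time < ep$t_start + 300]
  expect_lte(max(conc) - min(conc), 0.2 + 1e-9)
})

test_that("a drifting plateau yields no MOSSA epoch", {
  # hand-built trace drifting 0.3% over every 600-s window
  tt <- 0:1199
  sv <- tibble::tibble(time = tt, concentration = 2 + 0.001 * tt)
  rec <- make_recording(matrix(0, 1200 * 256, 1,
                               dimnames = list(NULL, "F7")))
  expect_message(eps <- extract_state_epochs(rec, sv, state = "MOSSA"),
                 "no qualifying")
  expect_length(eps, 0)
  # brute-force oracle agrees: no window passes the 0.1% rule
  ok <- vapply(1:600, function(i) {
    win <- sv$concentration[i:(i + 599)]
    max(abs(win - stats::median(win))) <= 0.1
  }, logical(1))
  expect_false(any(ok))
})

test_that("a recording without an awake segment yields no awake epoch", {
  tt <- 0:699
  sv <- tibble::tibble(time = tt, concentration = rep(2, 700))
  rec <- make_recording(matrix(0, 700 * 256, 1,
                               dimnames = list(NULL, "F7")))
  expect_message(eps <- extract_state_epochs(rec, sv, state = "awake"),
                 "no")
  expect_length(eps, 0)
})

test_that("first-movement extraction returns the paired epochs", {
  pre <- quick_preprocessed(seed = 33)
  eps <- extract_state_epochs(pre$rec, pre$sevo, pre$movement,
                              state = "first_movement")
  states <- vapply(eps, function(e) e$state, "")
  expect_setequal(states, c("MOSSA", "first_movement"))
  mv <- eps[[which(states == "first_movement")]]
  expect_equal(mv$t_start, pre$movement$t_first_movement)
  expect_gte(mv$duration, 5)
  expect_lte(mv$duration, 30)
})

test_that("emergence epochs stay inside their concentration bins", {
  # monotone decay 3.0 -> 0 over 20 min: every bin is populated
  tt <- 0:1199
  sv <- tibble::tibble(time = tt, concentration = 3.0 * (1 - tt / 1200))
  rec <- make_recording(matrix(rnorm(1200 * 256), ncol = 1,
                               dimnames = list(NULL, "F7")))
  eps <- bin_emergence_epochs(rec, sv)
  expect_length(eps, 10)
  expect_setequal(vapply(eps, function(e) e$etsevo_bin, 1L), 1:10)
  bins <- etsevo_bins()
  for (e in eps) {
    expect_equal(e$duration, 30)
    # per-sample membership oracle
    idx <- sv$time >= e$t_start & sv$time < e$t_start + e$duration
    cc <- sv$concentration[idx]
    expect_true(all(cc >= bins$lo[e$etsevo_bin] - 1e-9 &
                      cc < bins$hi[e$etsevo_bin]))
  }
})

test_that("a trace that never leaves the top bin populates only bin 10", {
  tt <- 0:599
  sv <- tibble::tibble(time = tt, concentration = rep(2.8, 600))
  rec <- make_recording(matrix(rnorm(600 * 256), ncol = 1,
                               dimnames = list(NULL, "F7")))
  eps <- bin_emergence_epochs(rec, sv)
  expect_length(eps, 1)
  expect_equal(eps[[1]]$etsevo_bin, 10L)
})

test_that("artifact masking flags spikes and rejects saturated epochs", {
  X <- matrix(rnorm(256 * 10, sd = 10), ncol = 2,
              dimnames = list(NULL, c("F7", "F8")))
  ep <- matrix_epoch(X)
  m <- artifact_mask(ep, 200)
  expect_false(any(m))
  expect_false(attr(m, "rejected"))
  spikes <- c(100, 900)
  ep$data[spikes, 2] <- 500
  m2 <- artifact_mask(ep, 200)
  expect_identical(which(m2), as.integer(spikes))
  ep$data[1:(0.2 * nrow(X)), 1] <- 400
  expect_true(attr(artifact_mask(ep, 200), "rejected"))
  expect_error(artifact_mask(ep, -1))
})

test_that("epochs stay inside the recording and MOSSA avoids induction", {
  for (seed in 1:12) {
    pre <- quick_preprocessed(paste0("B", seed),
                              age_group = if (seed %% 2) "4-6mo"
                                          else "0-3mo",
                              seed = seed)
    dur <- nrow(pre$rec$data) / pre$rec$fs
    tl <- pre$spec$timeline
    eps <- c(extract_state_epochs(pre$rec, pre$sevo, state = "MOSSA"),
             bin_emergence_epochs(pre$rec, pre$sevo))
    for (e in eps) {
      expect_gte(e$t_start, 0)
      expect_lte(e$t_start + e$duration, dur)
      if (e$state == "MOSSA") {
        expect_gte(e$t_start, tl$t_end[tl$state == "induction"])
      }
    }
  }
})
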