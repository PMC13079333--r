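make_signals <- function(x, fs = 1000) {
  tibble::tibble(time_s = (seq_along(x) - 1) / fs, ch1 = x)
}

test_that("offline envelope chain: zero in, zero out; stop-band rejection", {
  z <- emg_envelope(make_signals(rep(0, 3000)))
  expect_true(all(z$ch1 == 0))
  # a 1 Hz tone lies far below the 20 Hz band edge
  t <- (0:4999) / 1000
  tone <- emg_envelope(make_signals(sin(2 * pi * 1 * t)), normalize = "none")
  expect_lt(max(tone$ch1[500:4500]), 0.02)
})

test_that("offline envelope chain is zero-phase on a symmetric burst", {
  fs <- 1000
  t <- (0:5999) / fs
  centre <- 3
  burst <- exp(-0.5 * ((t - centre) / 0.15)^2) * cos(2 * pi * 80 * (t - centre))
  env <- emg_envelope(make_signals(burst), normalize = "none")
  expect_lte(abs(which.max(env$ch1) - (centre * fs + 1)), 1)
})

test_that("envelope errors: NaN input and too-low sampling rate", {
  expect_error(emg_envelope(make_signals(c(rep(0, 100), NA, rep(0, 100)))),
               "NA")
  slow <- tibble::tibble(time_s = (0:999) / 500, ch1 = rnorm(1000))
  expect_error(emg_envelope(slow), "too low")
})

test_that("preprocessed generator EMG recovers the true envelopes", {
  tr <- small_trial("momentum")
  env <- emg_envelope(tr$signals)
  co <- vapply(tr$config$muscle_names,
               function(m) cor(env[[m]], tr$envelopes[[m]]), numeric(1))
  expect_true(all(co >= 0.9))
  expect_true(all(as.matrix(env[tr$config$muscle_names]) >= 0))
  expect_equal(unname(apply(as.matrix(env[tr$config$muscle_names]), 2, max)),
               rep(1, 8))
})

test_that("Kalman filter converges to a constant input", {
  x <- kalman_filter(rep(2.5, 3000))
  expect_lt(abs(tail(x, 1) - 2.5), 0.025)
  expect_true(all(diff(x[1:200]) > 0))  # monotone rise toward the constant
})

test_that("Kalman filter trusts observations as observation noise vanishes", {
  set.seed(1)
  y <- rnorm(200)
  x <- kalman_filter(y, kalman_config(sigma_v2 = 1e-10))
  expect_lt(max(abs(x - y)), 1e-4)
})

test_that("Kalman step response matches an independent scalar recursion", {
  y <- c(rep(0, 200), rep(1, 800))
  got <- kalman_filter(y)
  # plain-R reference recursion, written directly from the state-space model
  G <- 1; F <- 1; q <- 0.1; r <- 10
  x <- 0; P <- 1
  ref <- numeric(length(y))
  for (t in seq_along(y)) {
    xp <- G * x; Pp <- G^2 * P + q
    K <- Pp * F / (F^2 * Pp + r)
    x <- xp + K * (y[t] - F * xp)
    P <- (1 - K * F) * Pp
    ref[t] <- x
  }
  expect_equal(got, ref, tolerance = 1e-12)
  # rise is monotone and crosses 0.5 at the reference's lag
  post <- got[201:1000]
  expect_true(all(diff(post) >= -1e-12))
  expect_equal(min(which(post >= 0.5)), min(which(ref[201:1000] >= 0.5)))
})

test_that("Kalman filter is strictly causal", {
  set.seed(2)
  y <- rnorm(500)
  a <- kalman_filter(y)
  y2 <- y
  y2[301:500] <- y2[301:500] + 100  # arbitrary future change
  b <- kalman_filter(y2)
  expect_equal(a[1:300], b[1:300])
  expect_error(kalman_config(sigma_b2 = 0), "positive")
})

test_that("block-average downsampling", {
  expect_equal(downsample_pool(1:10, 1000, 100), 5.5)
  expect_equal(downsample_pool(rep(3, 50), 1000, 100), rep(3, 5))
  expect_equal(downsample_pool(1:7, 1000, 1000), as.numeric(1:7))
  expect_error(downsample_pool(1:10, 1000, 300), "integer multiple")
  m <- matrix(1:20, ncol = 2)
  expect_equal(downsample_pool(m, 10, 2), rbind(c(3, 13), c(8, 18)))
})

test_that("causal envelope chain never uses future samples", {
  tr <- small_trial("momentum")
  sig <- tr$signals[1:4000, ]
  ones <- setNames(rep(1, 8), tr$config$muscle_names)
  a <- kalman_envelope(sig, scales = ones)
  sig2 <- sig
  sig2$VM[3001:4000] <- sig2$VM[3001:4000] * 5
  b <- kalman_envelope(sig2, scales = ones)
  expect_equal(a$VM[1:3000], b$VM[1:3000])
})
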