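test_that("generator is bit-identical under a fixed seed", {
  cfg <- synth_config(cycles_per_strategy = 1, rng_seed = 7)
  a <- generate_trial(cfg, "momentum")
  b <- generate_trial(cfg, "momentum")
  expect_identical(a$signals, b$signals)
  expect_identical(a$markers, b$markers)
  # a different strategy draws from a different stream
  c <- generate_trial(cfg, "stabilization")
  expect_false(isTRUE(all.equal(nrow(a$signals), nrow(c$signals))) &&
                 isTRUE(all.equal(a$signals$VM[1:100], c$signals$VM[1:100])))
})

test_that("cycle counts are honoured exactly", {
  tr <- small_trial("momentum")
  runs <- rle(as.character(tr$labels$state))
  expect_equal(sum(runs$values == "M-SiTSt"), 2)
  expect_equal(sum(runs$values == "M-StTSi"), 2)
  expect_equal(nrow(tr$transitions), 4)
  expect_equal(count_automaton_violations(tr$labels$state), 0L)
})

test_that("noiseless envelopes equal spatial . temporal exactly", {
  cfg <- synth_config(cycles_per_strategy = 1, envelope_noise_sd = 0,
                      baseline_envelope = 0, amp_jitter_sd = 0,
                      time_jitter_sd = 0)
  tr <- generate_trial(cfg, "momentum")
  W <- cfg$true_spatial
  H <- t(as.matrix(tr$temporal[colnames(W)]))
  env <- t(as.matrix(tr$envelopes[cfg$muscle_names]))
  expect_equal(env, W %*% H, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("invalid generator inputs error", {
  expect_error(generate_trial(synth_config(), "jumping"))
  expect_error(synth_config(hold_duration_s = 3), "at least 5")
  expect_error(synth_config(prep_lead_s = 0), "positive")
  expect_error(synth_config(transition_duration_s = c(momentum = -1,
                                                      stabilization = 2)),
               "positive")
  bad_W <- default_spatial() * 2
  expect_error(synth_config(true_spatial = bad_W), "max-normalized")
})

test_that("raw-EMG synthesis: zero and constant envelopes", {
  set.seed(5)
  z <- synthesize_raw_emg(rep(0, 5000), 1000, baseline_sd = 0.01)
  expect_lte(sqrt(mean(z^2)), 0.011)  # baseline noise only (5% sampling slack)
  expect_error(synthesize_raw_emg(c(-1, 1), 1000), "non-negative")
  # constant envelope: rectified-smoothed output is flat (CV < 0.2 over 12 s)
  x <- synthesize_raw_emg(rep(0.5, 12000), 1000, baseline_sd = 0.003)
  env <- emg_envelope(tibble::tibble(time_s = (0:11999) / 1000, ch = x),
                      normalize = "none")$ch
  mid <- env[1000:11000]
  expect_lt(stats::sd(mid) / mean(mid), 0.2)
  # and its level is proportional to the envelope (2/pi for a cosine carrier)
  expect_equal(mean(mid), 0.5 * 2 / pi, tolerance = 0.05)
})

test_that("hip height ramps monotonically inside each transition", {
  cfg <- synth_config(cycles_per_strategy = 2, hip_noise_sd = 0)
  tr <- generate_trial(cfg, "stabilization")
  for (i in seq_len(nrow(tr$transitions))) {
    idx <- tr$labels$time_s > tr$transitions$onset_s[i] &
      tr$labels$time_s <= tr$transitions$offset_s[i]
    h <- tr$markers$hip_height[idx]
    if (grepl("SiTSt", tr$transitions$type[i])) {
      expect_true(all(diff(h) > 0))
    } else {
      expect_true(all(diff(h) < 0))
    }
  }
  # holds are flat
  sit <- tr$labels$state == "Sitting"
  expect_lt(diff(range(tr$markers$hip_height[sit])), 1e-6 + 0.02)
})

test_that("stabilization bursts are lower and longer than momentum bursts", {
  cfg <- synth_config(cycles_per_strategy = 2, amp_jitter_sd = 0,
                      time_jitter_sd = 0)
  m <- generate_trial(cfg, "momentum")
  s <- generate_trial(cfg, "stabilization")
  peak <- function(tr, syn) max(tr$temporal[[syn]])
  dur_above <- function(tr, syn, frac = 0.5) {
    sum(tr$temporal[[syn]] > frac * peak(tr, syn)) / tr$fs /
      nrow(tr$transitions)
  }
  for (syn in c("E2", "E4")) {
    expect_lt(peak(s, syn), peak(m, syn))
    expect_gt(dur_above(s, syn), dur_above(m, syn))
  }
})

test_that("preparatory activation precedes the labelled onset", {
  cfg <- synth_config(cycles_per_strategy = 1, amp_jitter_sd = 0,
                      time_jitter_sd = 0, envelope_noise_sd = 0,
                      baseline_envelope = 0)
  tr <- generate_trial(cfg, "momentum")
  on_s <- tr$transitions$onset_s[tr$transitions$type == "M-SiTSt"]
  # E1 leads sit-to-stand: activation at the onset is already substantial,
  # and it starts rising close to prep_lead_s before the onset
  e1 <- tr$temporal$E1
  t <- tr$temporal$time_s
  i_on <- which.min(abs(t - on_s))
  expect_gt(e1[i_on], 0.04 * max(e1))
  first_active <- t[min(which(e1 > 0.05 * max(e1)))]
  expect_lt(first_active, on_s - 0.3 * cfg$prep_lead_s)
})
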