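# Shared lazily-built fixtures. Everything is generated in code under fixed
# seeds; expensive objects are cached for the duration of the test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# A small two-cycle trial, enough for envelope/segmentation checks.
small_trial <- function(strategy = "momentum") {
  cached(paste0("trial_", strategy), function() {
    generate_trial(synth_config(cycles_per_strategy = 2), strategy)
  })
}

# Offline activation envelopes of the small trial, 100 Hz, max-normalized.
small_activation <- function(strategy = "momentum") {
  cached(paste0("act_", strategy), function() {
    tr <- small_trial(strategy)
    env <- emg_envelope(tr$signals, normalize = "none")
    env100 <- downsample_pool(env, tr$fs, 100)
    chans <- setdiff(names(env100), "time_s")
    sc <- apply(as.matrix(env100[chans]), 2, max)
    env100[chans] <- sweep(as.matrix(env100[chans]), 2, sc, "/")
    env100
  })
}

small_labels <- function(strategy = "momentum") {
  cached(paste0("lab_", strategy), function() {
    tr <- small_trial(strategy)
    segment_states(downsample_pool(tr$markers, tr$fs, 100), strategy)
  })
}

# A tiny trained forecaster on well-separated two-state synthetic H.
# Returns the model plus the data used, for streaming-equivalence tests.
tiny_forecaster <- function() {
  cached("tiny_forecaster", function() {
    set.seed(7)
    n <- 600
    state <- rep(rep(c("Sitting", "Standing"), 3), each = 100)
    H <- tibble::tibble(
      time_s = (seq_len(n) - 1) / 100,
      Syn1 = ifelse(state == "Sitting", 1, 0) + rnorm(n, 0, 0.05),
      Syn2 = ifelse(state == "Standing", 1, 0) + rnorm(n, 0, 0.05)
    )
    labels <- factor(state, levels = sts_states("six"))
    # horizon 0: the task degenerates to current-state classification, so
    # it is fully separable (a positive horizon would make the frames just
    # before each state switch inherently ambiguous)
    cfg <- forecast_config(horizon_ms = 0, window_steps = 5,
                           strides = c(1, 2), hidden = 6, fc1 = 8,
                           buffer_len = 4, epochs = 200, batch_size = 200,
                           seed = 3)
    wd <- build_windows(H, labels, cfg)
    model <- train_forecaster(wd, wd, cfg)
    list(model = model, H = H, labels = labels, cfg = cfg, wd = wd)
  })
}
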