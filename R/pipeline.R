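# End-to-end pipeline: simulate -> preprocess -> segment -> synergy order
# selection and CNMF on the training split -> causal temporal-pattern
# estimation -> window building -> forecaster training -> streaming test
# prediction -> evaluation.

#' Pipeline configuration
#'
#' @param synth A [synth_config()] (the generator defines the study
#'   conditions; its `rng_seed` is overridden by `seed`).
#' @param kalman A [kalman_config()] for the causal envelope chain.
#' @param forecast A [forecast_config()]; defaults to the scaled-down
#'   training profile.
#' @param split Chronological train/validation/test fractions (must sum
#'   to 1); applied per strategy with boundaries snapped to static holds.
#' @param synergy_rate Working rate (Hz) for synergy analysis and
#'   forecasting; envelopes are block-averaged from the EMG rate.
#' @param order_restarts NMF restarts per candidate order in the model-order
#'   sweep.
#' @param nmf_restarts Restarts for the final synergy fit.
#' @param hard_filter Apply the hard automaton filter to test predictions.
#' @param out_dir Optional directory for persisted artifacts.
#' @param seed Integer master seed for every stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            kalman = kalman_config(),
                            forecast = forecast_config(profile = "scaled_down"),
                            split = c(train = 0.8, val = 0.1, test = 0.1),
                            synergy_rate = 100,
                            order_restarts = 5,
                            nmf_restarts = 20,
                            hard_filter = FALSE,
                            out_dir = NULL,
                            seed = 1) {
  split <- unname(split)
  if (length(split) != 3 || abs(sum(split) - 1) > 1e-8) {
    abort("`split` must be three fractions summing to 1")
  }
  structure(list(synth = synth, kalman = kalman, forecast = forecast,
                 split = c(train = split[1], val = split[2], test = split[3]),
                 synergy_rate = synergy_rate,
                 order_restarts = order_restarts,
                 nmf_restarts = nmf_restarts,
                 hard_filter = hard_filter, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Snap chronological split fractions to the midpoints of static-state runs
# so that no window or transition straddles a split boundary.
#' @noRd
snap_split <- function(labels, fracs) {
  x <- as.character(labels)
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  static <- which(r$values %in% c("Sitting", "Standing"))
  mids <- floor((starts[static] + ends[static]) / 2)
  cuts <- numeric(length(fracs))
  prev <- 0
  for (k in seq_along(fracs)) {
    cand <- mids[mids > prev]
    if (length(cand) == 0) abort("too few static holds to place split boundaries")
    target <- round(fracs[k] * n)
    prev <- cand[which.min(abs(cand - target))]
    cuts[k] <- prev
  }
  cuts
}

#' @noRd
normalize_channels <- function(x, scales) {
  chans <- signals_channels(x)
  x[chans] <- sweep(as.matrix(x[chans]), 2, scales[chans], "/")
  x
}

#' Extract per-motion activation segments
#'
#' Concatenates the activation frames around every transition of one motion
#' type (e.g. all sit-to-stand executions), including a margin before the
#' onset (to capture preparatory activation) and after the offset. This is
#' the per-motion, per-strategy dataset on which the motion-specific synergy
#' count is determined.
#'
#' @param A Activation tibble (`time_s` + channels).
#' @param labels State-label tibble from [segment_states()] (its
#'   `"transitions"` attribute provides the onsets/offsets).
#' @param motion `"SiTSt"` or `"StTSi"` (strategy tags are matched by
#'   suffix).
#' @param pad_before_s,pad_after_s Margins around each transition (s).
#' @return Activation tibble of the concatenated segments.
#' @export
motion_activation <- function(A, labels, motion = c("SiTSt", "StTSi"),
                              pad_before_s = 0.8, pad_after_s = 0.5) {
  motion <- match.arg(motion)
  trans <- attr(labels, "transitions")
  if (is.null(trans)) abort("`labels` carries no transitions attribute")
  trans <- trans[grepl(paste0(motion, "$"), trans$type), ]
  if (nrow(trans) == 0) abort(sprintf("no %s transitions in labels", motion))
  fs <- infer_fs(A$time_s)
  segs <- purrr::pmap(trans, function(type, onset_s, offset_s, ...) {
    i0 <- max(1L, floor((onset_s - pad_before_s) * fs) + 1L)
    i1 <- min(nrow(A), ceiling((offset_s + pad_after_s) * fs) + 1L)
    A[i0:i1, ]
  })
  concat_trials(segs)
}

#' Run the full analysis and forecasting pipeline
#'
#' Simulates the two-strategy corpus, derives ground-truth labels from the
#' hip trajectory, extracts offline activation envelopes, selects the
#' synergy count and fits spatial patterns by CNMF on the chronological
#' training split only, estimates causal temporal patterns with the fixed
#' spatial patterns over the Kalman-filtered envelopes, trains the
#' forecaster, stream-predicts the held-out test split, and evaluates.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @param keep_data Also return the per-strategy normalized 100 Hz
#'   activation envelopes and labels (for follow-up analyses such as
#'   per-motion synergy counts).
#' @return Object of class `sts_pipeline`: list with `eval` (an
#'   [evaluate_predictions()] report), `model`, `order` (the order-selection
#'   result), `synergy` (the final `synergy_model`), `scales`, `splits`,
#'   `predictions`, and the `config`.
#' @export
run_sts_pipeline <- function(config = pipeline_config(), verbose = TRUE,
                             keep_data = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  synth <- config$synth
  synth$rng_seed <- seed
  fc <- config$forecast
  fc$seed <- seed + 1L

  say("simulate: generating two-strategy corpus (seed %d)", seed)
  corpus <- simulate_corpus(synth)
  rate <- config$synergy_rate

  per <- purrr::imap(corpus, function(trial, strategy) {
    say("preprocess/segment: %s trial (%.0f s)", strategy,
        nrow(trial$signals) / trial$fs)
    markers_lo <- downsample_pool(trial$markers, trial$fs, rate)
    labels <- segment_states(markers_lo, strategy)
    env_off <- emg_envelope(trial$signals, normalize = "none")
    env100 <- downsample_pool(env_off, trial$fs, rate)
    ones <- setNames(rep(1, length(synth$muscle_names)), synth$muscle_names)
    env_cau <- kalman_envelope(trial$signals, config$kalman, scales = ones)
    cau100 <- downsample_pool(env_cau, trial$fs, rate)
    n <- min(nrow(env100), nrow(labels), nrow(cau100))
    cuts <- snap_split(labels$state[seq_len(n)],
                       c(config$split[["train"]],
                         config$split[["train"]] + config$split[["val"]]))
    list(labels = labels[seq_len(n), ], env100 = env100[seq_len(n), ],
         cau100 = cau100[seq_len(n), ], cuts = cuts, n = n,
         transitions = attr(labels, "transitions"))
  })

  # per-muscle normalization scales from the training split of both trials
  chans <- synth$muscle_names
  train_env <- dplyr::bind_rows(purrr::map(per, function(p) {
    p$env100[seq_len(p$cuts[1]), chans]
  }))
  scales <- apply(as.matrix(train_env), 2, max)
  scales[scales == 0] <- 1

  say("synergy: order selection and CNMF on the training split")
  A_train <- concat_trials(purrr::map(per, function(p) {
    normalize_channels(p$env100[seq_len(p$cuts[1]), ], scales)
  }))
  order_sel <- select_order(A_train, restarts = config$order_restarts,
                            seed = seed + 2L)
  say("synergy: selected n = %d (criterion %s)", order_sel$n,
      ifelse(order_sel$satisfied, "satisfied", "NOT satisfied"))
  syn_model <- fit_nmf(A_train, order_sel$n,
                       restarts = config$nmf_restarts, seed = seed + 3L)
  W <- syn_model$W

  say("temporal patterns: causal estimation under fixed spatial patterns")
  # Windows are built over each full recording; a window belongs to the
  # train/val/test part holding its TARGET frame. Input history may extend
  # before a split boundary -- exactly as a deployed stream would have a
  # warm buffer at that instant -- but no target label crosses a boundary.
  datasets <- list(train = list(), val = list(), test = list())
  full_wd <- list()
  for (strategy in names(per)) {
    p <- per[[strategy]]
    Hhat <- estimate_temporal(normalize_channels(p$cau100, scales), W)
    seg_base <- match(strategy, names(per)) * 10L
    wd <- build_windows(Hhat, p$labels$state, fc, segment = seg_base)
    target <- wd$t_index + wd$horizon_steps
    part_of <- cut(target, breaks = c(0, p$cuts, p$n),
                   labels = c("train", "val", "test"))
    for (part in c("train", "val", "test")) {
      idx <- which(part_of == part)
      if (length(idx) > 0) {
        datasets[[part]][[strategy]] <-
          subset_windowed(wd, idx, segment = seg_base + match(part, c("train", "val", "test")))
      }
    }
    full_wd[[strategy]] <- list(wd = wd, part_of = part_of, Hhat = Hhat,
                                labels = p$labels$state)
  }
  train_wd <- combine_windows(datasets$train)
  val_wd <- combine_windows(datasets$val)

  say("train: %d training windows, %d validation windows",
      length(train_wd$y), length(val_wd$y))
  model <- train_forecaster(train_wd, val_wd, fc, verbose = verbose)
  model$W_spatial <- W
  model$scales <- scales

  say("predict: streaming over held-out test ranges (warm buffers)")
  preds <- purrr::imap(full_wd, function(fw, strategy) {
    wd <- fw$wd
    lp <- stage1_logp(model$params, wd$X, model$I, model$H, model$F1,
                      model$C)
    N <- length(wd$t_index)
    buffer <- fc$buffer_len
    final <- rep(model$fallback, N)
    if (N > buffer) {
      feat <- fc2_feature_matrix(lp, buffer)
      z <- feat %*% model$fc2$W + rep(model$fc2$b, each = nrow(feat))
      final[(buffer + 1):N] <-
        model$classes[max.col(z, ties.method = "first")]
    }
    if (config$hard_filter) {
      final <- hard_transition_filter(final, init = model$fallback,
                                      scheme = fc$scheme)
    }
    keep <- which(fw$part_of == "test")
    target <- wd$t_index[keep] + wd$horizon_steps
    tibble::tibble(strategy = strategy,
                   time_s = fw$Hhat$time_s[target],
                   pred = factor(final[keep], levels = model$classes),
                   truth = fw$labels[target],
                   warmup = FALSE)
  })
  eval <- evaluate_predictions(purrr::map(preds, "pred"),
                               purrr::map(preds, "truth"),
                               fs = rate)
  say("evaluate: accuracy %.2f%%, mean |timing error| %.1f ms",
      eval$accuracy_percent, eval$timing_mean_abs_ms)

  splits <- purrr::imap_dfr(per, function(p, strategy) {
    tibble::tibble(strategy = strategy,
                   part = c("train", "val", "test"),
                   start = c(1L, p$cuts + 1L),
                   end = c(p$cuts, p$n))
  })
  result <- structure(list(
    eval = eval, model = model, order = order_sel, synergy = syn_model,
    scales = scales, splits = splits,
    predictions = dplyr::bind_rows(preds),
    per_strategy = purrr::map(per, function(p) {
      lab <- p$labels
      attr(lab, "transitions") <- p$transitions  # tibble subsetting drops it
      out <- list(labels = lab, transitions = p$transitions, n = p$n)
      if (keep_data) out$env100 <- normalize_channels(p$env100, scales)
      out
    }),
    config = config
  ), class = "sts_pipeline")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tidy(syn_model), file.path(config$out_dir, "spatial_patterns.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(order_sel$criteria, file.path(config$out_dir, "order_criteria.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(result$predictions, file.path(config$out_dir, "test_predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(tidy(eval), file.path(config$out_dir, "class_metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    saveRDS(model, file.path(config$out_dir, "forecaster.rds"))
    save_pipeline_config(config, file.path(config$out_dir, "pipeline_config.yaml"))
  }
  result
}

#' @export
print.sts_pipeline <- function(x, ...) {
  cat(sprintf("<sts_pipeline> synergy n=%d, test accuracy %.2f%%, mean |timing error| %.1f ms\n",
              x$order$n, x$eval$accuracy_percent, x$eval$timing_mean_abs_ms))
  invisible(x)
}
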