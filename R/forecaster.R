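# Multi-resolution recurrent forecaster of future motion state.
#
# Stage 1: four independent LSTM branches read the recent temporal-synergy
# activations H(t) at different temporal resolutions (average pooling with
# strides 1/2/4/8); their final hidden states are concatenated into a fully
# connected layer emitting log-probabilities of the state a forecast horizon
# ahead. Stage 2: a second fully connected layer reads a buffer of the
# previous stage-1 outputs and suppresses transitions that are implausible
# given the recent prediction history.

#' Forecaster configuration
#'
#' @param horizon_ms Forecast horizon: the network predicts the motion state
#'   this many milliseconds ahead (default 300).
#' @param window_steps Sequence length per LSTM branch (pooled steps).
#' @param strides Average-pooling strides of the branches; the branch with
#'   stride `s` covers `s * window_steps` input frames.
#' @param hidden Hidden units per LSTM branch.
#' @param fc1 Units in the first fully connected layer.
#' @param buffer_len Length of the stage-1 output buffer consumed by the
#'   second (transition-plausibility) layer.
#' @param scheme Label vocabulary, `"six"` (strategy-tagged) or `"four"`.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param lr_init,lr_final Learning rate, decayed linearly per epoch.
#' @param sgd_momentum Momentum coefficient of the SGD update.
#' @param clip Global gradient-norm clip.
#' @param class_weighting `"inverse"` (inverse-frequency class weights in the
#'   loss, the default -- transitions are rare relative to holds) or
#'   `"none"`.
#' @param window_stride Take every `window_stride`-th window as a stage-1
#'   training sample (stage-2 and all prediction always run frame by frame).
#' @param input_rate Rate of the input temporal patterns (Hz).
#' @param lookback `"full"` (each branch spans `stride * window_steps`
#'   frames, maximizing context; the default) or `"pooled_1s"` (all branches
#'   span `window_steps` frames, pooled to shorter sequences).
#' @param profile `NULL` or `"scaled_down"`: the scaled-down training profile
#'   (100 epochs, 10-step windows, strides 2/8/32/80, 24 hidden units,
#'   fc1 32, batch 256, window stride 3) used for desk-scale runs on clean
#'   synthetic data. The widened stride set keeps the slowest branch's
#'   context at 8 s -- the same span as the full profile -- which matters
#'   because only the previous transition burst disambiguates the two
#'   static holds; short sequences keep that burst within a few recurrent
#'   steps of the output.
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return List of class `forecast_config`.
#' @export
forecast_config <- function(horizon_ms = 300, window_steps = 100,
                            strides = c(1, 2, 4, 8), hidden = 128, fc1 = 128,
                            buffer_len = 15, scheme = c("six", "four"),
                            epochs = 1000, batch_size = 5000,
                            lr_init = 0.02, lr_final = 0.001,
                            sgd_momentum = 0.9, clip = 5,
                            class_weighting = c("inverse", "none"),
                            window_stride = 1, input_rate = 100,
                            lookback = c("full", "pooled_1s"),
                            profile = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  class_weighting <- match.arg(class_weighting)
  lookback <- match.arg(lookback)
  cfg <- list(horizon_ms = horizon_ms, window_steps = window_steps,
              strides = sort(strides), hidden = hidden, fc1 = fc1,
              buffer_len = buffer_len, scheme = scheme, epochs = epochs,
              batch_size = batch_size, lr_init = lr_init,
              lr_final = lr_final, sgd_momentum = sgd_momentum, clip = clip,
              class_weighting = class_weighting,
              window_stride = window_stride, input_rate = input_rate,
              lookback = lookback, seed = seed)
  if (!is.null(profile)) {
    profile <- match.arg(profile, "scaled_down")
    cfg[c("epochs", "window_steps", "strides", "hidden", "fc1", "batch_size",
          "window_stride")] <- list(100, 10, c(2, 8, 32, 80), 24, 32, 256, 3)
  }
  if (cfg$horizon_ms < 0) abort("`horizon_ms` must be non-negative")
  if (cfg$buffer_len < 1) abort("`buffer_len` must be at least 1")
  if (any(cfg$strides <= 0)) abort("strides must be positive")
  if (cfg$lookback == "pooled_1s" && cfg$window_steps < max(cfg$strides)) {
    # in the shared-window reading each branch pools w frames down to
    # w/stride steps, so the window must cover the largest stride
    abort("`window_steps` must be at least the largest stride")
  }
  structure(cfg, class = "forecast_config")
}

#' @noRd
horizon_steps <- function(config) {
  as.integer(round(config$horizon_ms * config$input_rate / 1000))
}

# Per-branch sequence length and frame span.
#' @noRd
branch_geometry <- function(config) {
  s <- config$strides
  w <- config$window_steps
  steps <- if (config$lookback == "full") rep(w, length(s)) else (w %/% s)
  if (any(steps < 1)) abort("window too short for the largest stride")
  tibble::tibble(stride = s, steps = steps, span = s * steps)
}

#' Build multi-resolution forecast windows
#'
#' For each frame `t` with a complete lookback, stacks the four pooled
#' input sequences `pool(H[t - s*steps + 1 .. t], stride s)` and the target
#' label `S(t + horizon)`. Frames whose lookback or target falls outside the
#' recording are dropped. The input `H` must be a single contiguous
#' recording segment (windows never cross segment boundaries; build one
#' dataset per segment and merge with [combine_windows()]).
#'
#' @param H Tibble of temporal synergy patterns: `time_s` plus one column
#'   per synergy, at `config$input_rate`.
#' @param labels Per-frame state labels aligned with `H` (factor, or tibble
#'   with a `state` column).
#' @param config A [forecast_config()].
#' @param segment Integer id of this segment.
#' @return Object of class `windowed_dataset`: list with `X` (one
#'   `N x I x steps` array per branch), `y` (factor of targets), `t_index`
#'   (prediction frame), `segment`, `classes`, geometry and config fields.
#' @export
build_windows <- function(H, labels, config = forecast_config(),
                          segment = 1L) {
  if (is.data.frame(labels)) labels <- labels$state
  syn <- signals_channels(H)
  Hm <- as.matrix(H[syn])
  T_ <- nrow(Hm)
  if (length(labels) != T_) abort("`labels` and `H` differ in length")
  if (!is.factor(labels)) labels <- factor(labels, levels = sts_states(config$scheme))
  geom <- branch_geometry(config)
  L <- max(geom$span)
  hs <- horizon_steps(config)
  if (T_ < L + hs + 1) {
    abort("recording shorter than lookback plus horizon")
  }
  t_index <- seq.int(L, T_ - hs)
  N <- length(t_index)
  I <- length(syn)
  cs <- apply(Hm, 2, cumsum)
  cs <- rbind(0, cs)  # cs[t + 1] = sum of rows 1..t
  X <- purrr::pmap(geom, function(stride, steps, span) {
    arr <- array(0, dim = c(N, I, steps))
    for (k in seq_len(steps)) {
      ends <- t_index - (steps - k) * stride
      arr[, , k] <- (cs[ends + 1, , drop = FALSE] -
                       cs[ends + 1 - stride, , drop = FALSE]) / stride
    }
    arr
  })
  structure(list(
    X = X, y = labels[t_index + hs], t_index = t_index,
    segment = rep(as.integer(segment), N),
    classes = levels(labels), synergies = syn,
    geometry = geom, horizon_steps = hs, lookback = L,
    input_rate = config$input_rate, scheme = config$scheme
  ), class = "windowed_dataset")
}

#' Merge windowed datasets from several segments
#'
#' @param datasets List of [build_windows()] results with identical geometry
#'   and class vocabulary.
#' @return Single `windowed_dataset`.
#' @export
combine_windows <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  d1 <- datasets[[1]]
  if (length(datasets) == 1) return(d1)
  for (d in datasets[-1]) {
    if (!identical(d$classes, d1$classes) ||
        !identical(d$geometry, d1$geometry)) {
      abort("datasets differ in geometry or classes")
    }
  }
  X <- purrr::map(seq_along(d1$X), function(b) {
    parts <- lapply(datasets, function(d) d$X[[b]])
    dims <- dim(parts[[1]])
    out <- array(0, dim = c(sum(vapply(parts, function(p) dim(p)[1], 0)),
                            dims[2], dims[3]))
    at <- 0L
    for (p in parts) {
      out[at + seq_len(dim(p)[1]), , ] <- p
      at <- at + dim(p)[1]
    }
    out
  })
  structure(list(
    X = X,
    y = factor(unlist(lapply(datasets, function(d) as.character(d$y))),
               levels = d1$classes),
    t_index = unlist(lapply(datasets, function(d) d$t_index)),
    segment = unlist(lapply(datasets, function(d) d$segment)),
    classes = d1$classes, synergies = d1$synergies,
    geometry = d1$geometry, horizon_steps = d1$horizon_steps,
    lookback = d1$lookback, input_rate = d1$input_rate, scheme = d1$scheme
  ), class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d samples, %d branches, horizon %d steps\n",
              length(x$y), length(x$X), x$horizon_steps))
  invisible(x)
}

# Row subset of a windowed dataset (keeps geometry and vocabulary).
#' @noRd
subset_windowed <- function(wd, idx, segment = NULL) {
  n <- if (is.logical(idx)) sum(idx) else length(idx)
  structure(list(
    X = lapply(wd$X, function(a) a[idx, , , drop = FALSE]),
    y = wd$y[idx], t_index = wd$t_index[idx],
    segment = if (is.null(segment)) wd$segment[idx] else
      rep(as.integer(segment), n),
    classes = wd$classes, synergies = wd$synergies,
    geometry = wd$geometry, horizon_steps = wd$horizon_steps,
    lookback = wd$lookback, input_rate = wd$input_rate,
    scheme = wd$scheme), class = "windowed_dataset")
}

#' @noRd
n_params <- function(I, H, F1, C, B = 4) {
  B * (4 * H * (I + H + 1)) + (B * H) * F1 + F1 + F1 * C + C
}

#' @noRd
init_params <- function(I, H, F1, C, B = 4) {
  r_lstm <- 1 / sqrt(H)
  p <- c()
  for (b in seq_len(B)) {
    p <- c(p, runif(I * 4 * H, -r_lstm, r_lstm),
           runif(H * 4 * H, -r_lstm, r_lstm),
           c(rep(0, H), rep(1, H), rep(0, 2 * H)))  # forget-gate bias 1
  }
  p <- c(p, runif(B * H * F1, -1 / sqrt(B * H), 1 / sqrt(B * H)), rep(0, F1),
         runif(F1 * C, -1 / sqrt(F1), 1 / sqrt(F1)), rep(0, C))
  p
}

#' @noRd
subset_windows <- function(data, idx) {
  list(X = lapply(data$X, function(a) a[idx, , , drop = FALSE]),
       y = data$y[idx])
}

#' @noRd
stage1_logp <- function(params, X, I, H, F1, C, chunk = 8192) {
  N <- dim(X[[1]])[1]
  out <- matrix(0, N, C)
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    Xc <- lapply(X, function(a) a[idx, , , drop = FALSE])
    out[idx, ] <- forecaster_forward_cpp(params, Xc, I, H, F1, C)
  }
  out
}

# Stage-2 feature rows: for each row j > buffer of a per-segment stage-1
# log-probability matrix, the flattened buffer [logp(j-buffer) .. logp(j)].
#' @noRd
fc2_feature_matrix <- function(logp, buffer) {
  N <- nrow(logp); C <- ncol(logp)
  if (N <= buffer) return(NULL)
  rows <- (buffer + 1):N
  feat <- matrix(0, length(rows), (buffer + 1) * C)
  for (o in buffer:0) {
    feat[, (buffer - o) * C + seq_len(C)] <- logp[rows - o, , drop = FALSE]
  }
  feat
}

#' @noRd
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weighted-NLL softmax regression for the stage-2 layer (deterministic
# full-batch gradient descent with momentum from a zero initialization).
#' @noRd
train_fc2 <- function(feat, y_int, w_class, C, iters = 400, lr = 0.5,
                      mom = 0.9) {
  D <- ncol(feat)
  W <- matrix(0, D, C); b <- rep(0, C)
  vW <- W; vb <- b
  wi <- w_class[y_int]
  wsum <- sum(wi)
  Yind <- cbind(seq_along(y_int), y_int)
  for (it in seq_len(iters)) {
    P <- softmax_rows(feat %*% W + rep(b, each = nrow(feat)))
    G <- P
    G[Yind] <- G[Yind] - 1
    G <- G * (wi / wsum)
    gW <- crossprod(feat, G)
    gb <- colSums(G)
    step <- lr * (1 - 0.8 * (it - 1) / iters)
    vW <- mom * vW - step * gW; vb <- mom * vb - step * gb
    W <- W + vW; b <- b + vb
  }
  list(W = W, b = b)
}

#' Train the multi-resolution motion-state forecaster
#'
#' Stage 1 (the recurrent classifier) is trained by minibatch SGD with
#' momentum on the class-weighted negative log-likelihood, with the learning
#' rate decayed linearly from `lr_init` to `lr_final`; the parameters with
#' the best validation accuracy are kept. Stage 2 (the
#' transition-plausibility layer) is then trained on teacher-forced buffers
#' of frozen stage-1 outputs with the same weighted loss. Fully
#' deterministic given `config$seed`.
#'
#' @param train,val [combine_windows()]/[build_windows()] datasets built at
#'   window stride 1 (stage-1 SGD subsamples internally by
#'   `config$window_stride`).
#' @param config A [forecast_config()].
#' @param verbose Print a progress line every 10 epochs.
#' @return Object of class `sts_forecaster`.
#' @export
train_forecaster <- function(train, val = NULL, config = forecast_config(),
                             verbose = FALSE) {
  y <- train$y
  present <- levels(y)[tabulate(y, length(levels(y))) > 0]
  if (length(present) < 2) abort("training data contain fewer than 2 classes")
  C <- length(levels(y))
  I <- length(train$synergies)
  H <- config$hidden; F1 <- config$fc1
  freq <- tabulate(y, C)
  w_class <- if (config$class_weighting == "inverse") {
    w <- ifelse(freq > 0, sum(freq) / pmax(freq, 1), 0)
    w / mean(w[freq > 0])
  } else {
    ifelse(freq > 0, 1, 0)
  }
  y_int <- as.integer(y)

  with_local_seed(config$seed, {
    params <- init_params(I, H, F1, C, B = length(config$strides))
    vel <- numeric(length(params))
    universe <- which((seq_along(y) %% config$window_stride) == 0L)
    log_rows <- vector("list", config$epochs)
    best <- list(acc = -Inf, params = params)
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr_init + (config$lr_final - config$lr_init) *
        (epoch - 1) / max(config$epochs - 1, 1)
      idx <- sample(universe)
      losses <- c()
      for (start in seq(1, length(idx), by = config$batch_size)) {
        bi <- idx[start:min(start + config$batch_size - 1, length(idx))]
        Xb <- lapply(train$X, function(a) a[bi, , , drop = FALSE])
        g <- forecaster_grad_cpp(params, Xb, y_int[bi] - 1L, w_class,
                                 I, H, F1, C)
        if (!is.finite(g$loss)) {
          abort(sprintf("non-finite training loss at epoch %d", epoch))
        }
        gn <- sqrt(sum(g$grad^2))
        gvec <- if (gn > config$clip) g$grad * (config$clip / gn) else g$grad
        vel <- config$sgd_momentum * vel - lr * gvec
        params <- params + vel
        losses <- c(losses, g$loss)
      }
      val_acc <- NA_real_
      if (!is.null(val)) {
        lp <- stage1_logp(params, val$X, I, H, F1, C)
        val_acc <- 100 * mean(max.col(lp, ties.method = "first") ==
                                as.integer(val$y))
        if (val_acc > best$acc) best <- list(acc = val_acc, params = params)
      }
      log_rows[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                          loss = mean(losses),
                                          val_accuracy = val_acc)
      if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
        message(sprintf("epoch %4d  loss %.4f  val %.2f%%", epoch,
                        mean(losses), val_acc))
      }
    }
    if (!is.null(val) && is.finite(best$acc)) params <- best$params

    # stage 2: teacher-forced buffers of frozen stage-1 outputs
    lp_train <- stage1_logp(params, train$X, I, H, F1, C)
    feats <- list(); targs <- list()
    for (sg in unique(train$segment)) {
      rows <- which(train$segment == sg)
      fm <- fc2_feature_matrix(lp_train[rows, , drop = FALSE],
                               config$buffer_len)
      if (is.null(fm)) next
      feats[[length(feats) + 1]] <- fm
      targs[[length(targs) + 1]] <-
        y_int[rows][(config$buffer_len + 1):length(rows)]
    }
    feat <- do.call(rbind, feats)
    targ <- unlist(targs)
    fc2 <- train_fc2(feat, targ, w_class, C)

    fallback <- levels(y)[which.max(freq)]
    structure(list(
      params = params, I = I, H = H, F1 = F1, C = C,
      classes = levels(y), class_weights = w_class, fc2 = fc2,
      config = config, fallback = fallback,
      log = dplyr::bind_rows(log_rows),
      best_val_accuracy = if (is.null(val)) NA_real_ else best$acc
    ), class = "sts_forecaster")
  })
}

#' @export
print.sts_forecaster <- function(x, ...) {
  cat(sprintf("<sts_forecaster> %d classes, %d LSTM branches x %d hidden, horizon %d ms\n",
              x$C, length(x$config$strides), x$H, x$config$horizon_ms))
  if (is.finite(x$best_val_accuracy)) {
    cat(sprintf("  best validation accuracy: %.2f%%\n", x$best_val_accuracy))
  }
  invisible(x)
}

#' Apply the learned transition-plausibility layer
#'
#' Maps a buffer of previous stage-1 outputs plus the current stage-1 output
#' to the final state estimate. This is the learned second-stage layer; for
#' the hard automaton variant see [hard_transition_filter()].
#'
#' @param model A trained [train_forecaster()] model.
#' @param logp_history Numeric matrix `buffer_len x C` of the previous
#'   stage-1 log-probability rows (oldest first).
#' @param logp_current Numeric vector of the current stage-1
#'   log-probabilities.
#' @return The final state label (character scalar).
#' @export
apply_transition_filter <- function(model, logp_history, logp_current) {
  stopifnot(inherits(model, "sts_forecaster"))
  if (nrow(logp_history) != model$config$buffer_len) {
    abort("history length must equal the configured buffer length")
  }
  # flatten row-wise: [oldest .. newest, current], each C wide
  feat <- matrix(as.numeric(t(rbind(logp_history, logp_current))), nrow = 1)
  z <- feat %*% model$fc2$W + model$fc2$b
  model$classes[which.max(z)]
}

#' Batch prediction over a contiguous recording segment
#'
#' Runs the full two-stage forecaster over every frame of a contiguous
#' temporal-pattern segment. Frames before the lookback or stage-2 buffer is
#' filled emit the training-majority fallback label flagged as warm-up.
#' Equivalent label-for-label to feeding the segment through
#' [stream_step()].
#'
#' @param model A trained `sts_forecaster`.
#' @param H Temporal-pattern tibble (`time_s` + synergy columns) for one
#'   contiguous segment.
#' @param hard_filter Apply the hard automaton post-filter to the final
#'   labels (off by default; the learned stage-2 layer is the primary
#'   mechanism).
#' @return Tibble with columns `t_index` (prediction frame), `time_s`,
#'   `target_index` (forecast frame `t + horizon`), `stage1`, `pred`
#'   (factors) and `warmup`.
#' @export
predict_batch <- function(model, H, hard_filter = FALSE) {
  stopifnot(inherits(model, "sts_forecaster"))
  cfg <- model$config
  syn <- signals_channels(H)
  T_ <- nrow(H)
  dummy <- factor(rep(model$classes[1], T_), levels = model$classes)
  wd <- build_windows(H, dummy, cfg)
  lp <- stage1_logp(model$params, wd$X, model$I, model$H, model$F1, model$C)
  stage1 <- model$classes[max.col(lp, ties.method = "first")]
  N <- length(wd$t_index)
  buffer <- cfg$buffer_len
  final <- rep(model$fallback, N)
  warm <- rep(TRUE, N)
  if (N > buffer) {
    feat <- fc2_feature_matrix(lp, buffer)
    z <- feat %*% model$fc2$W + rep(model$fc2$b, each = nrow(feat))
    final[(buffer + 1):N] <- model$classes[max.col(z, ties.method = "first")]
    warm[(buffer + 1):N] <- FALSE
  }
  if (hard_filter) {
    final <- hard_transition_filter(final, init = model$fallback,
                                    scheme = cfg$scheme)
  }
  tibble::tibble(
    t_index = wd$t_index,
    time_s = H$time_s[wd$t_index],
    target_index = wd$t_index + wd$horizon_steps,
    stage1 = factor(stage1, levels = model$classes),
    pred = factor(final, levels = model$classes),
    warmup = warm
  )
}

#' Initialize a real-time prediction stream
#'
#' @param model A trained `sts_forecaster`.
#' @param hard_filter Apply the hard automaton filter to emitted labels.
#' @return An environment holding the stream state; pass to [stream_step()].
#' @export
stream_init <- function(model, hard_filter = FALSE) {
  stopifnot(inherits(model, "sts_forecaster"))
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$hard_filter <- hard_filter
  geom <- branch_geometry(model$config)
  st$L <- max(geom$span)
  st$geom <- geom
  st$csum <- matrix(0, st$L + 1, model$I)  # ring of running cumulative sums
  st$run_total <- rep(0, model$I)
  st$t <- 0L
  st$lp_buf <- matrix(NA_real_, model$config$buffer_len, model$C)
  st$lp_n <- 0L
  st$prev <- model$fallback
  st
}

#' Advance the prediction stream by one frame
#'
#' Strictly causal: consumes one frame of temporal-pattern values and emits
#' the forecast of the state `horizon_ms` ahead. Until the lookback and the
#' stage-2 buffer are filled, the training-majority fallback label is
#' emitted with `warmup = TRUE`.
#'
#' @param st Stream state from [stream_init()].
#' @param h_step Numeric vector: one frame of temporal synergy patterns.
#' @return List with `label`, `stage1`, `logp` and `warmup`.
#' @export
stream_step <- function(st, h_step) {
  model <- st$model
  st$t <- st$t + 1L
  st$run_total <- st$run_total + as.numeric(h_step)
  st$csum[(st$t %% (st$L + 1)) + 1L, ] <- st$run_total
  if (st$t < st$L) {
    return(list(label = st$prev, stage1 = NA_character_, logp = NULL,
                warmup = TRUE))
  }
  cs_at <- function(tt) st$csum[(tt %% (st$L + 1)) + 1L, ]  # valid for tt >= t - L
  X <- purrr::pmap(st$geom, function(stride, steps, span) {
    arr <- array(0, dim = c(1, model$I, steps))
    for (k in seq_len(steps)) {
      e <- st$t - (steps - k) * stride
      arr[1, , k] <- (cs_at(e) - cs_at(e - stride)) / stride
    }
    arr
  })
  lp <- forecaster_forward_cpp(model$params, X, model$I, model$H, model$F1,
                               model$C)
  stage1 <- model$classes[which.max(lp)]
  buffer <- model$config$buffer_len
  if (st$lp_n < buffer) {
    st$lp_buf[st$lp_n + 1L, ] <- lp
    st$lp_n <- st$lp_n + 1L
    return(list(label = st$prev, stage1 = stage1, logp = drop(lp),
                warmup = TRUE))
  }
  feat <- matrix(as.numeric(t(rbind(st$lp_buf, lp))), nrow = 1)
  z <- feat %*% model$fc2$W + model$fc2$b
  label <- model$classes[which.max(z)]
  st$lp_buf <- rbind(st$lp_buf[-1, , drop = FALSE], lp)
  if (st$hard_filter) {
    key <- paste(st$prev, label, sep = "->")
    allowed <- sts_transitions(model$config$scheme)
    if (!key %in% paste(allowed$from, allowed$to, sep = "->")) {
      label <- st$prev
    }
  }
  st$prev <- label
  list(label = label, stage1 = stage1, logp = drop(lp), warmup = FALSE)
}
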