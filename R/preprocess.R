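#' @noRd
signals_channels <- function(signals) {
  stopifnot(is.data.frame(signals))
  if (!"time_s" %in% names(signals)) {
    abort("`signals` must contain a `time_s` column")
  }
  setdiff(names(signals), "time_s")
}

#' Infer the sampling rate from a time vector
#'
#' @param time_s Strictly increasing numeric vector of sample times (s).
#' @param tol Relative tolerance on sampling-interval regularity.
#' @return Sampling rate in Hz.
#' @export
infer_fs <- function(time_s, tol = 0.01) {
  if (length(time_s) < 2) abort("need at least two samples to infer fs")
  dt <- diff(time_s)
  if (any(dt <= 0)) abort("`time_s` must be strictly increasing")
  dmed <- median(dt)
  if (any(abs(dt - dmed) > tol * dmed)) {
    abort("irregular sampling: time deltas deviate by more than the tolerance")
  }
  1 / dmed
}

# Zero-phase Butterworth with odd-reflection end padding (filtfilt alone
# starts from zero initial conditions and distorts both ends).
#' @noRd
butter_filtfilt <- function(x, w, type, order = 4) {
  flt <- signal::butter(order, w, type = type)
  n <- length(x)
  npad <- min(n - 1, max(60, 3 * ceiling(2 / min(w))))
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- signal::filtfilt(flt, c(pre, x, post))
  y[(npad + 1):(npad + n)]
}

#' Offline EMG activation envelopes (zero-phase chain)
#'
#' Converts raw multi-channel EMG to non-negative activation envelopes using
#' the offline chain: zero-phase Butterworth band-pass (default 20--450 Hz,
#' applied as cascaded high-pass and low-pass sections), full-wave
#' rectification, zero-phase Butterworth low-pass at 4 Hz, clamping of tiny
#' filter-induced negatives to zero, and per-muscle max normalization.
#'
#' @param signals Tibble with a `time_s` column and one numeric column per
#'   muscle channel.
#' @param band Band-pass edges in Hz.
#' @param lowpass Envelope low-pass cutoff in Hz.
#' @param order Butterworth order for each section (applied forward-backward,
#'   so the effective order doubles).
#' @param normalize One of `"max"` (per-muscle maximum scaled to 1, the
#'   default) or `"none"`.
#' @param scales Optional named vector of per-muscle scale factors to divide
#'   by instead of each channel's own maximum (e.g. scales estimated on a
#'   training split).
#' @return Tibble of the same shape as `signals` with envelope values; the
#'   per-muscle scale factors used are attached as attribute `"scales"`.
#' @export
emg_envelope <- function(signals, band = c(20, 450), lowpass = 4, order = 4,
                         normalize = c("max", "none"), scales = NULL) {
  normalize <- match.arg(normalize)
  chans <- signals_channels(signals)
  fs <- infer_fs(signals$time_s)
  if (fs / 2 <= band[2]) {
    abort(sprintf("sampling rate %.0f Hz too low for a %.0f Hz band edge",
                  fs, band[2]))
  }
  mat <- as.matrix(signals[chans])
  if (anyNA(mat) || any(!is.finite(mat))) abort("signals contain NA or non-finite values")
  env <- apply(mat, 2, function(x) {
    x <- butter_filtfilt(x, band[1] / (fs / 2), "high", order)
    x <- butter_filtfilt(x, band[2] / (fs / 2), "low", order)
    x <- abs(x)
    x <- butter_filtfilt(x, lowpass / (fs / 2), "low", order)
    pmax(x, 0)
  })
  sc <- rep(1, length(chans))
  names(sc) <- chans
  if (!is.null(scales)) {
    if (!all(chans %in% names(scales))) abort("`scales` must name every channel")
    sc <- scales[chans]
  } else if (normalize == "max") {
    sc <- apply(env, 2, max)
    if (any(sc == 0)) sc[sc == 0] <- 1
  }
  env <- sweep(env, 2, sc, "/")
  out <- dplyr::bind_cols(tibble::tibble(time_s = signals$time_s),
                          tibble::as_tibble(env))
  attr(out, "scales") <- sc
  attr(out, "fs") <- fs
  out
}

#' Kalman filter configuration
#'
#' Scalar random-walk Kalman model used for causal (real-time) envelope
#' smoothing in place of the zero-phase 4 Hz low-pass:
#' state `x_t = G x_{t-1} + w_t` with `w_t ~ N(0, sigma_b2)`, observation
#' `y_t = F x_t + v_t` with `v_t ~ N(0, sigma_v2)`. The default process noise
#' is small (0.1) and the observation noise large (10), so the filter tracks
#' slow trends while suppressing the heavy sample-to-sample fluctuation of
#' rectified EMG.
#'
#' @param G,F State-transition and observation scalars.
#' @param sigma_b2 Process-noise variance (> 0).
#' @param sigma_v2 Observation-noise variance (> 0).
#' @param x0,P0 Initial state and covariance.
#' @return List of class `kalman_config`.
#' @export
kalman_config <- function(G = 1, F = 1, sigma_b2 = 0.1, sigma_v2 = 10,
                          x0 = 0, P0 = 1) {
  if (sigma_b2 <= 0 || sigma_v2 <= 0) abort("noise variances must be positive")
  structure(list(G = G, F = F, sigma_b2 = sigma_b2, sigma_v2 = sigma_v2,
                 x0 = x0, P0 = P0),
            class = "kalman_config")
}

#' Causal scalar Kalman filter
#'
#' Strictly causal per-sample recursion: the output at index `t` depends
#' only on observations up to `t`.
#'
#' @param x Numeric vector of observations.
#' @param config A [kalman_config()].
#' @return Numeric vector of filtered estimates, same length as `x`.
#' @export
kalman_filter <- function(x, config = kalman_config()) {
  stopifnot(inherits(config, "kalman_config"))
  if (anyNA(x) || any(!is.finite(x))) abort("signal contains NA or non-finite values")
  as.numeric(kalman_filter_cpp(as.numeric(x), config$G, config$F,
                               config$sigma_b2, config$sigma_v2,
                               config$x0, config$P0))
}

#' Causal EMG activation envelopes (real-time chain)
#'
#' Real-time substitute for [emg_envelope()]: causal Butterworth band-pass
#' (forward-only), full-wave rectification, per-channel causal Kalman
#' smoothing, and normalization by supplied per-muscle scales (typically the
#' scales recorded on a training split). No future samples are used.
#'
#' @inheritParams emg_envelope
#' @param config A [kalman_config()].
#' @param scales Named per-muscle scale factors to divide by; if `NULL`, each
#'   channel's own maximum is used (offline calibration).
#' @return Tibble like `signals` with non-negative causal envelope values.
#' @export
kalman_envelope <- function(signals, config = kalman_config(),
                            band = c(20, 450), order = 4, scales = NULL) {
  chans <- signals_channels(signals)
  fs <- infer_fs(signals$time_s)
  if (fs / 2 <= band[2]) {
    abort(sprintf("sampling rate %.0f Hz too low for a %.0f Hz band edge",
                  fs, band[2]))
  }
  hp <- signal::butter(order, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(order, band[2] / (fs / 2), type = "low")
  mat <- as.matrix(signals[chans])
  env <- apply(mat, 2, function(x) {
    x <- signal::filter(hp, x)
    x <- signal::filter(lp, x)
    pmax(kalman_filter(abs(x), config), 0)
  })
  if (is.null(scales)) {
    scales <- apply(env, 2, max)
    scales[scales == 0] <- 1
    names(scales) <- chans
  }
  env <- sweep(env, 2, scales[chans], "/")
  out <- dplyr::bind_cols(tibble::tibble(time_s = signals$time_s),
                          tibble::as_tibble(env))
  attr(out, "scales") <- scales[chans]
  attr(out, "fs") <- fs
  out
}

#' Block-average downsampling
#'
#' Non-overlapping block averaging from `in_fs` to `out_fs`; `in_fs` must be
#' an integer multiple of `out_fs`. Trailing samples that do not fill a
#' complete block are dropped.
#'
#' @param x Tibble with `time_s` plus channel columns, a numeric matrix
#'   (time in rows), or a numeric vector.
#' @param in_fs,out_fs Input and output sampling rates in Hz.
#' @return Object of the same kind as `x`, at rate `out_fs`. For tibbles the
#'   `time_s` column is the block-mean time.
#' @export
downsample_pool <- function(x, in_fs, out_fs) {
  r <- in_fs / out_fs
  if (abs(r - round(r)) > 1e-9) {
    abort("`in_fs` must be an integer multiple of `out_fs`")
  }
  r <- as.integer(round(r))
  pool_mat <- function(m) {
    n <- (nrow(m) %/% r) * r
    m <- m[seq_len(n), , drop = FALSE]
    grp <- rep(seq_len(n %/% r), each = r)
    out <- rowsum(m, grp, reorder = FALSE) / r
    dimnames(out) <- if (is.null(colnames(m))) NULL else
      list(NULL, colnames(m))
    out
  }
  if (is.data.frame(x)) {
    m <- pool_mat(as.matrix(x))
    tibble::as_tibble(m)
  } else if (is.matrix(x)) {
    pool_mat(x)
  } else {
    as.numeric(pool_mat(matrix(as.numeric(x), ncol = 1)))
  }
}
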