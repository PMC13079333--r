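#' Default latent spatial synergy patterns
#'
#' Encodes the qualitative synergy memberships of the sit-to-stand repertoire
#' over the eight recorded muscles: E1 (ankle dorsiflexion, early sit-to-stand:
#' TA with RF, ES), E2 (knee extension: VM, RF, VL), E3 (late stand-to-sit
#' balance / ankle plantarflexion: ES with TA, VM, RF) and E4 (hip extension:
#' ST, SOL, Gmed with ES). Dominant muscles weigh 1.0 and secondary muscles
#' 0.5, except that E3's overlap with E1 (TA, RF) is kept minor (0.2/0.3):
#' if E3 dominated a scaled copy of E1 elementwise, a scaled E1 could be
#' moved in or out of E3 with an exactly unchanged product, so the latent
#' patterns would not be recoverable even from noiseless data. Each column
#' is max-normalized to 1. The exact weights are free generator parameters,
#' not empirical estimates.
#'
#' @param muscle_names Character vector of 8 muscle identifiers.
#' @return 8 x 4 non-negative matrix with muscle row names and synergy
#'   column names `E1`..`E4`.
#' @export
default_spatial <- function(muscle_names = c("VM", "RF", "VL", "ST",
                                             "TA", "SOL", "Gmed", "ES")) {
  W <- matrix(0, 8, 4, dimnames = list(muscle_names, paste0("E", 1:4)))
  W[c("TA", "RF", "ES"), "E1"] <- c(1.0, 0.5, 0.5)
  W[c("VM", "RF", "VL"), "E2"] <- c(1.0, 1.0, 1.0)
  W[c("ES", "TA", "VM", "RF"), "E3"] <- c(1.0, 0.2, 0.5, 0.3)
  W[c("ST", "SOL", "Gmed", "ES"), "E4"] <- c(1.0, 1.0, 1.0, 0.5)
  W
}

#' Synthetic-trial generator configuration
#'
#' Defines the study conditions emulated by the generator: an 8-muscle EMG
#' montage whose activation envelopes arise from 4 latent synergies with
#' strategy-dependent amplitude, duration and timing; a repeating
#' Sitting -> SiTSt -> Standing -> StTSi cycle with static holds of at least
#' 5 s; preparatory synergy activation beginning `prep_lead_s` before the
#' hip leaves its plateau; and a hip-height trajectory for segmentation.
#'
#' @param muscle_names Eight muscle identifiers.
#' @param true_spatial Non-negative 8 x 4 matrix of latent spatial patterns,
#'   each column max-normalized to 1.
#' @param cycles_per_strategy Number of full sit-stand-sit cycles per trial.
#' @param hold_duration_s Minimum static hold duration (s, must be >= 5).
#' @param hold_jitter_s Uniform jitter added to each hold duration (s).
#' @param transition_duration_s Named numeric: labelled transition duration
#'   per strategy (s).
#' @param prep_lead_s Lead time of preparatory activation before the
#'   labelled transition onset (s, > 0).
#' @param amplitude_scale,width_scale Named numeric per strategy: peak
#'   amplitude and activation-width multipliers relative to the momentum
#'   defaults (the stabilization strategy uses lower, longer activations).
#' @param amp_jitter_sd Relative SD of per-burst amplitude jitter.
#' @param time_jitter_sd SD of per-burst peak-time jitter (s).
#' @param emg_fs EMG sampling rate (Hz, >= 1000).
#' @param envelope_noise_sd SD of additive smooth (4 Hz band) envelope noise
#'   on the max-normalized activation scale.
#' @param baseline_envelope Tonic non-negative envelope offset per muscle.
#' @param carrier_freq_range Instantaneous-frequency range of the EMG
#'   carrier (Hz), inside the 20--450 Hz analysis band.
#' @param carrier_baseline_sd SD of additive wide-band measurement noise on
#'   the raw EMG scale.
#' @param hip_sit,hip_stand Hip-marker heights in the two static postures
#'   (arbitrary length units).
#' @param hip_noise_sd SD of hip-marker jitter (same units).
#' @param rng_seed Integer seed; identical seed and config give bit-identical
#'   output.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(muscle_names = c("VM", "RF", "VL", "ST",
                                          "TA", "SOL", "Gmed", "ES"),
                         true_spatial = default_spatial(muscle_names),
                         cycles_per_strategy = 10,
                         hold_duration_s = 5,
                         hold_jitter_s = 0.5,
                         transition_duration_s = c(momentum = 1.2,
                                                   stabilization = 2.4),
                         prep_lead_s = 0.5,
                         amplitude_scale = c(momentum = 1, stabilization = 0.6),
                         width_scale = c(momentum = 1, stabilization = 1.6),
                         amp_jitter_sd = 0.1,
                         time_jitter_sd = 0.03,
                         emg_fs = 1000,
                         envelope_noise_sd = 0.002,
                         baseline_envelope = 0.005,
                         carrier_freq_range = c(60, 350),
                         carrier_baseline_sd = 0.003,
                         hip_sit = 0.45, hip_stand = 0.95,
                         hip_noise_sd = 0.002,
                         rng_seed = 1L) {
  if (length(muscle_names) != 8) abort("exactly 8 muscle names are required")
  if (ncol(true_spatial) != 4) abort("`true_spatial` must have 4 columns")
  if (any(true_spatial < 0)) abort("`true_spatial` must be non-negative")
  cmax <- apply(true_spatial, 2, max)
  if (any(abs(cmax - 1) > 1e-8)) {
    abort("each `true_spatial` column must be max-normalized to 1")
  }
  if (prep_lead_s <= 0) abort("`prep_lead_s` must be positive")
  if (hold_duration_s < 5) abort("`hold_duration_s` must be at least 5 s")
  if (any(transition_duration_s <= 0)) abort("transition durations must be positive")
  if (emg_fs < 1000) abort("`emg_fs` must be at least 1000 Hz")
  rownames(true_spatial) <- muscle_names
  structure(list(
    muscle_names = muscle_names, true_spatial = true_spatial,
    cycles_per_strategy = cycles_per_strategy,
    hold_duration_s = hold_duration_s, hold_jitter_s = hold_jitter_s,
    transition_duration_s = transition_duration_s, prep_lead_s = prep_lead_s,
    amplitude_scale = amplitude_scale, width_scale = width_scale,
    amp_jitter_sd = amp_jitter_sd, time_jitter_sd = time_jitter_sd,
    emg_fs = emg_fs, envelope_noise_sd = envelope_noise_sd,
    baseline_envelope = baseline_envelope,
    carrier_freq_range = carrier_freq_range,
    carrier_baseline_sd = carrier_baseline_sd,
    hip_sit = hip_sit, hip_stand = hip_stand, hip_noise_sd = hip_noise_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "synth_config")
}

# Evaluate an expression under a local RNG seed, restoring the caller's
# random state afterwards.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Quintic smoothstep: monotone C^2 ramp that is exactly flat outside [0, 1].
#' @noRd
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^3 * (10 - 15 * x + 6 * x^2)
}

# Fraction of the ramp at which smoothstep crosses `level` (e.g. 0.02).
#' @noRd
smoothstep_crossing <- function(level) {
  uniroot(function(x) smoothstep(x) - level, c(0, 1), tol = 1e-12)$root
}

#' Synthesize raw surface EMG from an activation envelope
#'
#' Produces a zero-mean, band-limited stochastic carrier amplitude-modulated
#' by the envelope, plus additive wide-band baseline noise. The carrier is a
#' constant-amplitude cosine whose instantaneous frequency wanders slowly
#' inside `carrier_freq_range`; its rectified mean is exactly
#' `2/pi * envelope`, with ripple harmonics at twice the carrier frequency
#' that the 4 Hz envelope low-pass removes. The rectified-and-smoothed raw
#' signal is therefore proportional to the envelope.
#'
#' @param envelope Non-negative numeric vector.
#' @param fs Sampling rate in Hz (>= 1000).
#' @param carrier_freq_range Instantaneous-frequency range (Hz).
#' @param baseline_sd SD of additive Gaussian baseline noise.
#' @return Numeric vector of raw EMG samples, same length as `envelope`.
#' @export
synthesize_raw_emg <- function(envelope, fs, carrier_freq_range = c(60, 350),
                               baseline_sd = 0.003) {
  if (any(envelope < 0)) abort("`envelope` must be non-negative")
  if (fs < 1000) abort("`fs` must be at least 1000 Hz")
  n <- length(envelope)
  # slowly wandering instantaneous frequency (OU-smoothed white noise)
  e <- rnorm(n)
  u <- as.numeric(stats::filter(e, 0.995, method = "recursive"))
  u <- (u - mean(u)) / max(stats::sd(u), 1e-12)
  f <- carrier_freq_range[1] +
    (carrier_freq_range[2] - carrier_freq_range[1]) * stats::pnorm(u)
  phase <- 2 * pi * cumsum(f) / fs + runif(1, 0, 2 * pi)
  envelope * cos(phase) + rnorm(n, 0, baseline_sd)
}

#' Generate one synthetic sit-to-stand trial
#'
#' Builds a full recording for one strategy: `cycles_per_strategy` repetitions
#' of Sitting -> SiTSt -> Standing -> StTSi with jittered holds, a smooth hip
#' ramp per transition, latent temporal synergy activations (Gaussian bursts
#' in the strategy- and motion-specific order: E1, E2, E4 within SiTSt and
#' E4, E2, E3 within StTSi), envelopes `true_spatial %*% true_temporal` plus
#' tonic baseline and smooth noise, and amplitude-modulated raw EMG.
#' Preparatory activation of the leading synergy begins `prep_lead_s` before
#' the labelled transition onset. Ground-truth labels place transition
#' onset/offset at the 2\%/98\% crossings of the hip ramp, the same
#' convention [segment_states()] detects.
#'
#' @param config A [synth_config()].
#' @param strategy `"momentum"` or `"stabilization"`.
#' @return List of class `sts_trial` with elements `signals` (raw EMG
#'   tibble), `envelopes` (true envelopes), `temporal` (true latent
#'   activations), `markers` (hip height), `labels` (per-frame six-class
#'   state), `transitions` (ground-truth onset/offset times per transition),
#'   `spatial` (the latent spatial patterns), `strategy`, `fs`, `config`.
#' @export
generate_trial <- function(config = synth_config(),
                           strategy = c("momentum", "stabilization")) {
  stopifnot(inherits(config, "synth_config"))
  strategy <- match.arg(strategy)
  seed <- config$rng_seed + ifelse(strategy == "momentum", 0L, 104729L)
  with_local_seed(seed, generate_trial_impl(config, strategy))
}

#' @noRd
generate_trial_impl <- function(config, strategy) {
  fs <- config$emg_fs
  ncyc <- config$cycles_per_strategy
  D <- unname(config$transition_duration_s[strategy])
  x02 <- smoothstep_crossing(0.02)
  ramp_len <- D / (1 - 2 * x02)      # hip ramp spans the label window plus margin
  ramp_pad <- x02 * ramp_len

  hold <- function() config$hold_duration_s + runif(1, 0, config$hold_jitter_s)

  # lay out segment boundaries
  transitions <- list()
  t_cur <- hold()
  for (k in seq_len(ncyc)) {
    for (type in c("SiTSt", "StTSi")) {
      transitions[[length(transitions) + 1]] <-
        list(type = type, t_on = t_cur, t_off = t_cur + D)
      t_cur <- t_cur + D + hold()
    }
  }
  total_s <- t_cur
  n <- floor(total_s * fs)
  time_s <- (seq_len(n) - 1) / fs

  # hip trajectory
  hip <- rep(config$hip_sit, n)
  tag <- if (strategy == "momentum") "M-" else "S-"
  trans_tbl <- purrr::map_dfr(transitions, function(tr) {
    t0 <- tr$t_on - ramp_pad
    xx <- (time_s - t0) / ramp_len
    ramp <- smoothstep(xx) * (config$hip_stand - config$hip_sit)
    if (tr$type == "SiTSt") hip <<- hip + ramp else hip <<- hip - ramp
    tibble::tibble(type = paste0(tag, tr$type),
                   onset_s = tr$t_on, offset_s = tr$t_off)
  })
  # ground-truth labels: transition frames lie in (onset, offset]; static
  # segments alternate Sitting/Standing between them
  level <- "Sitting"
  bounds <- c(0, unlist(lapply(transitions, function(tr) c(tr$t_on, tr$t_off))),
              total_s + 1 / fs)
  seg_lab <- character(0)
  for (tr in transitions) {
    seg_lab <- c(seg_lab, level, paste0(tag, tr$type))
    level <- ifelse(tr$type == "SiTSt", "Standing", "Sitting")
  }
  seg_lab <- c(seg_lab, level)
  seg_idx <- findInterval(time_s, bounds, left.open = TRUE) # 1..length(seg_lab)
  state <- seg_lab[pmax(seg_idx, 1)]
  hip <- hip + rnorm(n, 0, config$hip_noise_sd)

  # latent temporal activations: Gaussian bursts in motion-specific order
  H <- matrix(0, 4, n, dimnames = list(colnames(config$true_spatial), NULL))
  amp0 <- unname(config$amplitude_scale[strategy])
  wscale <- unname(config$width_scale[strategy])
  D_mom <- unname(config$transition_duration_s["momentum"])
  # burst width: narrow enough that successive bursts within a transition
  # are temporally separable (the latent factorization is identifiable),
  # wide enough to overlap its neighbours' tails
  sd_other <- 0.12 * D_mom * wscale
  sd_lead <- (0.10 * D + config$prep_lead_s) / 2.5
  for (tr in transitions) {
    if (tr$type == "SiTSt") {
      bursts <- list(c(syn = 1, frac = 0.10, sd = sd_lead),
                     c(syn = 2, frac = 0.45, sd = sd_other),
                     c(syn = 4, frac = 0.80, sd = sd_other))
    } else {
      bursts <- list(c(syn = 4, frac = 0.10, sd = sd_lead),
                     c(syn = 2, frac = 0.50, sd = sd_other),
                     c(syn = 3, frac = 0.85, sd = sd_other))
    }
    for (b in bursts) {
      centre <- tr$t_on + b[["frac"]] * D + rnorm(1, 0, config$time_jitter_sd)
      amp <- amp0 * max(0.5, 1 + rnorm(1, 0, config$amp_jitter_sd))
      sdv <- b[["sd"]]
      lo <- max(1L, floor((centre - 4 * sdv) * fs))
      hi <- min(n, ceiling((centre + 4 * sdv) * fs))
      idx <- lo:hi
      H[b[["syn"]], idx] <- H[b[["syn"]], idx] +
        amp * exp(-0.5 * ((time_s[idx] - centre) / sdv)^2)
    }
  }

  # envelopes = spatial . temporal + tonic baseline + smooth noise
  env <- config$true_spatial %*% H + config$baseline_envelope
  if (config$envelope_noise_sd > 0) {
    noise <- vapply(seq_len(nrow(env)), function(i) {
      z <- butter_filtfilt(rnorm(n), 4 / (fs / 2), "low")
      z / max(stats::sd(z), 1e-12) * config$envelope_noise_sd
    }, numeric(n))
    env <- env + t(noise)
  }
  env <- pmax(env, 0)

  raw <- vapply(seq_len(nrow(env)), function(i) {
    synthesize_raw_emg(env[i, ], fs, config$carrier_freq_range,
                       config$carrier_baseline_sd)
  }, numeric(n))
  colnames(raw) <- config$muscle_names

  env_t <- t(env)
  colnames(env_t) <- config$muscle_names
  structure(list(
    signals = dplyr::bind_cols(tibble::tibble(time_s = time_s),
                               tibble::as_tibble(raw)),
    envelopes = dplyr::bind_cols(tibble::tibble(time_s = time_s),
                                 tibble::as_tibble(env_t)),
    temporal = dplyr::bind_cols(tibble::tibble(time_s = time_s),
                                tibble::as_tibble(t(H))),
    markers = tibble::tibble(time_s = time_s, hip_height = hip),
    labels = tibble::tibble(time_s = time_s,
                            state = factor(state, levels = sts_states("six")),
                            strategy = strategy),
    transitions = trans_tbl,
    spatial = config$true_spatial,
    strategy = strategy, fs = fs, config = config
  ), class = "sts_trial")
}

#' @export
print.sts_trial <- function(x, ...) {
  cat(sprintf("<sts_trial> strategy=%s, %.1f s at %d Hz, %d transitions\n",
              x$strategy, nrow(x$signals) / x$fs, as.integer(x$fs),
              nrow(x$transitions)))
  invisible(x)
}

#' Generate the default two-strategy corpus
#'
#' One momentum-transfer trial and one stabilization trial from the same
#' configuration (strategy-specific RNG streams derived from `rng_seed`).
#'
#' @param config A [synth_config()].
#' @return Named list with elements `momentum` and `stabilization`, each an
#'   `sts_trial`.
#' @export
simulate_corpus <- function(config = synth_config()) {
  list(momentum = generate_trial(config, "momentum"),
       stabilization = generate_trial(config, "stabilization"))
}
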