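#' Segment motion states from the hip-height trajectory
#'
#' Derives ground-truth motion-state labels from the vertical hip-marker
#' trajectory. The trajectory is smoothed with a zero-phase 4 Hz low-pass,
#' the two plateau levels (sitting and standing hip height) are estimated by
#' robust medians, and each frame is labelled by its position relative to a
#' tolerance band of `band_frac` times the sit-stand span around each
#' plateau: frames inside the low band are `Sitting`, inside the high band
#' `Standing`, and frames between the bands are transition frames labelled
#' `SiTSt` or `StTSi` by the direction of the height change. The transition
#' onset is thus the first sample that leaves the pre-transition plateau
#' band and the offset the last sample before the post-transition band --
#' the same convention the synthetic generator uses for its ground truth.
#'
#' @param markers Tibble with columns `time_s` and `hip_height`.
#' @param strategy Optional strategy tag (`"momentum"` or `"stabilization"`);
#'   when supplied, transition labels are strategy-tagged (six-class scheme).
#' @param band_frac Plateau tolerance band as a fraction of the sit-stand
#'   span (default 0.02).
#' @param smooth_hz Zero-phase low-pass cutoff applied before segmentation.
#' @return Tibble with columns `time_s`, `state` (factor), `strategy`; the
#'   detected transitions (type, onset, offset) are attached as attribute
#'   `"transitions"`. A flat trajectory yields all-`Sitting` labels with a
#'   warning.
#' @export
segment_states <- function(markers, strategy = NULL, band_frac = 0.02,
                           smooth_hz = 4) {
  stopifnot(all(c("time_s", "hip_height") %in% names(markers)))
  h_raw <- markers$hip_height
  if (any(!is.finite(h_raw))) abort("hip_height contains non-finite values")
  fs <- infer_fs(markers$time_s)
  n <- length(h_raw)
  h <- if (smooth_hz < fs / 2) {
    butter_filtfilt(h_raw, smooth_hz / (fs / 2), "low")
  } else {
    h_raw
  }

  scheme <- if (is.null(strategy)) "four" else "six"
  tag <- if (is.null(strategy)) {
    ""
  } else {
    c(momentum = "M-", stabilization = "S-")[[strategy]]
  }

  mid <- (max(h) + min(h)) / 2
  lo_level <- median(h[h <= mid])
  hi_level <- median(h[h > mid])
  span <- hi_level - lo_level
  noise <- stats::mad(diff(h_raw)) / sqrt(2)
  if (!is.finite(span) || span <= 5 * noise || span <= 1e-12) {
    warn("flat hip trajectory: no transitions found, labelling all frames static")
    out <- tibble::tibble(
      time_s = markers$time_s,
      state = factor(rep("Sitting", n), levels = sts_states(scheme)),
      strategy = if (is.null(strategy)) NA_character_ else strategy
    )
    attr(out, "transitions") <-
      tibble::tibble(type = character(), onset_s = numeric(),
                     offset_s = numeric())
    return(out)
  }

  band <- band_frac * span
  zone <- ifelse(h <= lo_level + band, "low",
                 ifelse(h >= hi_level - band, "high", "mid"))
  state <- character(n)
  state[zone == "low"] <- "Sitting"
  state[zone == "high"] <- "Standing"

  r <- rle(zone)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  trans <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] != "mid") next
    i0 <- starts[k]; i1 <- ends[k]
    before <- if (k > 1) r$values[k - 1] else NA
    after <- if (k < length(r$values)) r$values[k + 1] else NA
    up <- h[i1] > h[i0]
    type <- if (up) "SiTSt" else "StTSi"
    # require a genuine plateau-to-plateau crossing where context exists
    if (!is.na(before) && !is.na(after) && before == after) {
      # excursion that returns to the same plateau: treat as plateau noise
      state[i0:i1] <- if (before == "low") "Sitting" else "Standing"
      next
    }
    lab <- paste0(tag, type)
    state[i0:i1] <- lab
    trans[[length(trans) + 1]] <-
      tibble::tibble(type = lab, onset_s = markers$time_s[i0],
                     offset_s = markers$time_s[i1])
  }

  out <- tibble::tibble(
    time_s = markers$time_s,
    state = factor(state, levels = sts_states(scheme)),
    strategy = if (is.null(strategy)) NA_character_ else strategy
  )
  attr(out, "transitions") <- if (length(trans) > 0) {
    dplyr::bind_rows(trans)
  } else {
    tibble::tibble(type = character(), onset_s = numeric(),
                   offset_s = numeric())
  }
  attr(out, "fs") <- fs
  out
}
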