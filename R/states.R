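#' Motion-state vocabularies
#'
#' The sit-to-stand cycle is described by four motion states --
#' `Sitting`, `SiTSt` (sit-to-stand), `Standing`, `StTSi` (stand-to-sit) --
#' repeating cyclically. In the six-class scheme the two transition states
#' carry a strategy tag: `M-` for the momentum-transfer strategy and `S-`
#' for the stabilization strategy; the static states are shared.
#'
#' @param scheme `"six"` (strategy-tagged transitions, the default working
#'   vocabulary) or `"four"`.
#' @return Character vector of state labels, in cycle order.
#' @export
#' @examples
#' sts_states("four")
sts_states <- function(scheme = c("six", "four")) {
  scheme <- match.arg(scheme)
  if (scheme == "four") {
    c("Sitting", "SiTSt", "Standing", "StTSi")
  } else {
    c("Sitting", "M-SiTSt", "S-SiTSt", "Standing", "M-StTSi", "S-StTSi")
  }
}

#' Collapse strategy-tagged labels to the four-state scheme
#'
#' Deterministically maps `M-SiTSt`/`S-SiTSt` to `SiTSt` and
#' `M-StTSi`/`S-StTSi` to `StTSi`; static states pass through.
#'
#' @param labels Character vector or factor of six-class (or already
#'   four-class) state labels.
#' @return Factor with levels `sts_states("four")`.
#' @export
collapse_states <- function(labels) {
  x <- as.character(labels)
  x <- sub("^[MS]-", "", x)
  bad <- setdiff(unique(x), sts_states("four"))
  if (length(bad) > 0) {
    abort(paste0("unknown state label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = sts_states("four"))
}

#' Allowed state transitions of the sit-to-stand cycle
#'
#' Self-transitions are always allowed. Cross-transitions follow the cyclic
#' automaton Sitting -> SiTSt -> Standing -> StTSi -> Sitting; in the
#' six-class scheme either strategy's transition state may follow a static
#' state, but a transition segment keeps its strategy until the next static
#' state.
#'
#' @inheritParams sts_states
#' @return Tibble with columns `from`, `to`.
#' @export
sts_transitions <- function(scheme = c("six", "four")) {
  scheme <- match.arg(scheme)
  states <- sts_states(scheme)
  if (scheme == "four") {
    cross <- tibble::tibble(
      from = c("Sitting", "SiTSt", "Standing", "StTSi"),
      to   = c("SiTSt", "Standing", "StTSi", "Sitting")
    )
  } else {
    cross <- tibble::tibble(
      from = c("Sitting", "Sitting", "M-SiTSt", "S-SiTSt",
               "Standing", "Standing", "M-StTSi", "S-StTSi"),
      to   = c("M-SiTSt", "S-SiTSt", "Standing", "Standing",
               "M-StTSi", "S-StTSi", "Sitting", "Sitting")
    )
  }
  dplyr::bind_rows(tibble::tibble(from = states, to = states), cross)
}

#' Count automaton violations in a label sequence
#'
#' @param labels Vector of state labels.
#' @inheritParams sts_states
#' @return Integer count of consecutive pairs that are not allowed
#'   transitions.
#' @export
count_automaton_violations <- function(labels, scheme = c("six", "four")) {
  scheme <- match.arg(scheme)
  x <- as.character(labels)
  if (length(x) < 2) return(0L)
  allowed <- sts_transitions(scheme)
  key <- paste(x[-length(x)], x[-1], sep = "->")
  ok <- key %in% paste(allowed$from, allowed$to, sep = "->")
  sum(!ok)
}

#' Hard transition-plausibility filter
#'
#' Sequentially replaces any emission that would violate the cyclic
#' automaton with the previous accepted label. This is the optional "safety
#' mode" alternative to the learned second-stage classifier: with it on, the
#' output stream contains zero impossible transitions by construction.
#'
#' @param labels Proposed label sequence (character or factor).
#' @param init Initial accepted state; defaults to the first label.
#' @inheritParams sts_states
#' @return Character vector of filtered labels, same length as `labels`.
#' @export
hard_transition_filter <- function(labels, init = NULL,
                                   scheme = c("six", "four")) {
  scheme <- match.arg(scheme)
  x <- as.character(labels)
  if (length(x) == 0) return(character())
  allowed <- sts_transitions(scheme)
  key <- paste(allowed$from, allowed$to, sep = "->")
  prev <- if (is.null(init)) x[1] else as.character(init)
  out <- character(length(x))
  for (i in seq_along(x)) {
    cand <- x[i]
    if (paste(prev, cand, sep = "->") %in% key) prev <- cand
    out[i] <- prev
  }
  out
}
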