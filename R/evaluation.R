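# Frame-wise performance measures for motion-state prediction: accuracy,
# one-vs-rest class metrics, transition timing error, frame-wise false
# detection rate, and row-normalized confusion matrices.

#' @noRd
as_label_chr <- function(x) {
  if (is.data.frame(x)) x <- x$state
  as.character(x)
}

#' Frame-wise prediction accuracy
#'
#' `100 * (matching frames / N)` with Kronecker-delta matching.
#'
#' @param pred,truth Label vectors (or tibbles with a `state` column) of
#'   equal length.
#' @return Accuracy in percent.
#' @export
frame_accuracy <- function(pred, truth) {
  p <- as_label_chr(pred); s <- as_label_chr(truth)
  if (length(p) != length(s)) abort("`pred` and `truth` differ in length")
  if (length(p) == 0) abort("empty sequences")
  100 * mean(p == s)
}

#' Class-wise precision, recall and F1
#'
#' One-vs-rest TP/FP/FN per class. F1 is set to 0 when precision + recall
#' is 0 (the usual convention for a class that is predicted but never
#' correctly); a class absent from both `pred` and `truth` gets `NA`
#' metrics rather than 0.
#'
#' @inheritParams frame_accuracy
#' @param classes Class vocabulary; defaults to the union of observed labels
#'   (factor levels are used when available).
#' @return Tibble with columns `class`, `n_truth`, `precision`, `recall`,
#'   `f1`.
#' @export
class_metrics <- function(pred, truth, classes = NULL) {
  p <- as_label_chr(pred); s <- as_label_chr(truth)
  if (length(p) != length(s)) abort("`pred` and `truth` differ in length")
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth) else sort(unique(c(p, s)))
  }
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(p == cl & s == cl)
    fp <- sum(p == cl & s != cl)
    fn <- sum(p != cl & s == cl)
    if (tp + fp + fn == 0) {
      return(tibble::tibble(class = cl, n_truth = 0L, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = cl, n_truth = tp + fn, precision = prec,
                   recall = rec, f1 = f1)
  })
}

#' @noRd
transition_onsets <- function(labels, time_s) {
  x <- as.character(labels)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  is_trans <- grepl("SiTSt|StTSi", r$values)
  keep <- which(is_trans & starts > 1)  # a run starting at frame 1 has no onset
  tibble::tibble(type = r$values[keep], onset_s = time_s[starts[keep]])
}

#' Signed transition timing errors
#'
#' For each ground-truth transition onset, finds the nearest predicted onset
#' of the same transition type within a search window and reports the signed
#' error `predicted - truth` in milliseconds (positive = late prediction).
#' Ground-truth onsets with no same-type predicted onset inside the window
#' are counted as misses and excluded from the error list; predicted onsets
#' that match no truth onset are spurious detections.
#'
#' @inheritParams frame_accuracy
#' @param fs Sampling rate of the label sequences (Hz).
#' @param window_s Search half-window around each true onset (s).
#' @return Tibble of class onsets: columns `type`, `truth_s`, `pred_s`,
#'   `error_ms`, `matched`; the miss count and spurious count are attached
#'   as attributes `"misses"` and `"spurious"`.
#' @export
transition_timing_error <- function(pred, truth, fs, window_s = 1) {
  p <- as_label_chr(pred); s <- as_label_chr(truth)
  if (length(p) != length(s)) abort("`pred` and `truth` differ in length")
  time_s <- (seq_along(p) - 1) / fs
  ons_p <- transition_onsets(p, time_s)
  ons_t <- transition_onsets(s, time_s)
  used <- rep(FALSE, nrow(ons_p))
  rows <- purrr::map_dfr(seq_len(nrow(ons_t)), function(i) {
    cand <- which(ons_p$type == ons_t$type[i] &
                    abs(ons_p$onset_s - ons_t$onset_s[i]) <= window_s)
    if (length(cand) == 0) {
      return(tibble::tibble(type = ons_t$type[i], truth_s = ons_t$onset_s[i],
                            pred_s = NA_real_, error_ms = NA_real_,
                            matched = FALSE))
    }
    j <- cand[which.min(abs(ons_p$onset_s[cand] - ons_t$onset_s[i]))]
    used[j] <<- TRUE
    tibble::tibble(type = ons_t$type[i], truth_s = ons_t$onset_s[i],
                   pred_s = ons_p$onset_s[j],
                   error_ms = 1000 * (ons_p$onset_s[j] - ons_t$onset_s[i]),
                   matched = TRUE)
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(type = character(), truth_s = numeric(),
                           pred_s = numeric(), error_ms = numeric(),
                           matched = logical())
  }
  attr(rows, "misses") <- sum(!rows$matched)
  attr(rows, "spurious") <- sum(!used)
  rows
}

#' Frame-wise false detection rate
#'
#' Fraction (percent) of frames whose ground truth is `from_state` but which
#' are predicted as `transition_state` -- e.g. Sitting frames falsely
#' predicted as sit-to-stand, the safety-critical error for assistive
#' devices.
#'
#' @inheritParams frame_accuracy
#' @param from_state Ground-truth static state (e.g. `"Sitting"`).
#' @param transition_state Falsely detected transition state (e.g.
#'   `"SiTSt"`); a vector is allowed (counts are pooled), which covers the
#'   strategy-tagged scheme where either strategy's transition counts.
#' @return FDR in percent.
#' @export
false_detection_rate <- function(pred, truth, from_state, transition_state) {
  p <- as_label_chr(pred); s <- as_label_chr(truth)
  if (length(p) != length(s)) abort("`pred` and `truth` differ in length")
  denom <- sum(s %in% from_state)
  if (denom == 0) abort(sprintf("no frames with ground truth %s",
                                paste(from_state, collapse = "/")))
  100 * sum(s %in% from_state & p %in% transition_state) / denom
}

#' Row-normalized confusion matrix
#'
#' Counts predictions against ground truth and normalizes each row
#' (ground-truth class) to percentages summing to 100. Rows for classes
#' absent from the ground truth are `NA`.
#'
#' @inheritParams frame_accuracy
#' @param classes Class vocabulary (row/column order).
#' @return List of class `sts_confusion` with `counts` and `percent`
#'   matrices (rows = truth, columns = prediction).
#' @export
confusion_matrix_norm <- function(pred, truth, classes = NULL) {
  p <- as_label_chr(pred); s <- as_label_chr(truth)
  if (length(p) != length(s)) abort("`pred` and `truth` differ in length")
  if (is.null(classes)) {
    classes <- if (is.factor(truth)) levels(truth) else sort(unique(c(p, s)))
  }
  counts <- table(factor(s, levels = classes), factor(p, levels = classes))
  counts <- unclass(as.matrix(counts))
  rs <- rowSums(counts)
  percent <- counts / ifelse(rs == 0, NA_real_, rs) * 100
  structure(list(counts = counts, percent = percent, classes = classes),
            class = "sts_confusion")
}

#' @export
print.sts_confusion <- function(x, digits = 1, ...) {
  cat("Row-normalized confusion matrix (%):\n")
  print(round(x$percent, digits))
  invisible(x)
}

#' Full evaluation report for a prediction stream
#'
#' Computes the complete measurement set on one or more aligned
#' prediction/truth segment pairs: frame-wise accuracy, per-class
#' precision/recall/F1, row-normalized confusion matrix, signed transition
#' timing errors (per segment, pooled), and the safety-relevant frame-wise
#' false detection rates (static state misread as the following transition).
#'
#' @param pred,truth Label vectors, or lists of label vectors (one per
#'   contiguous segment; timing errors never span segments).
#' @param fs Sampling rate of the label streams (Hz).
#' @param classes Class vocabulary; defaults to factor levels of truth.
#' @return Object of class `sts_eval`.
#' @export
evaluate_predictions <- function(pred, truth, fs, classes = NULL) {
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  p_all <- unlist(lapply(pred, as_label_chr))
  t_all <- unlist(lapply(truth, as_label_chr))
  if (is.null(classes)) {
    classes <- if (is.factor(truth[[1]])) levels(truth[[1]]) else
      sort(unique(c(p_all, t_all)))
  }
  timing <- purrr::map_dfr(seq_along(pred), function(i) {
    tt <- transition_timing_error(pred[[i]], truth[[i]], fs)
    tt$segment <- i
    tt
  })
  misses <- sum(is.na(timing$error_ms))
  fdr <- purrr::map_dfr(
    list(c(from = "Sitting", to = "SiTSt"), c(from = "Standing", to = "StTSi")),
    function(pair) {
      to_states <- grep(pair[["to"]], classes, value = TRUE)
      if (!pair[["from"]] %in% t_all) return(NULL)
      tibble::tibble(
        from_state = pair[["from"]],
        transition_state = paste(to_states, collapse = "|"),
        n_from = sum(t_all == pair[["from"]]),
        n_false = sum(t_all == pair[["from"]] & p_all %in% to_states),
        fdr_percent = false_detection_rate(p_all, t_all, pair[["from"]],
                                           to_states)
      )
    })
  err <- timing$error_ms[timing$matched]
  structure(list(
    accuracy_percent = frame_accuracy(p_all, t_all),
    metrics = class_metrics(p_all, t_all, classes),
    confusion = confusion_matrix_norm(p_all, t_all, classes),
    timing = timing,
    timing_mean_ms = if (length(err)) mean(err) else NA_real_,
    timing_sd_ms = if (length(err) > 1) stats::sd(err) else NA_real_,
    timing_mean_abs_ms = if (length(err)) mean(abs(err)) else NA_real_,
    misses = misses,
    fdr = fdr,
    n = length(p_all),
    fs = fs, classes = classes
  ), class = "sts_eval")
}

#' @export
print.sts_eval <- function(x, ...) {
  cat(sprintf("<sts_eval> N=%d frames, accuracy %.2f%%\n", x$n,
              x$accuracy_percent))
  cat(sprintf("  transition timing: mean %+.1f ms (sd %.1f), mean |err| %.1f ms, %d missed\n",
              x$timing_mean_ms, x$timing_sd_ms, x$timing_mean_abs_ms, x$misses))
  if (nrow(x$fdr) > 0) {
    for (i in seq_len(nrow(x$fdr))) {
      cat(sprintf("  FDR %s->%s: %.2f%% (%d/%d)\n", x$fdr$from_state[i],
                  x$fdr$transition_state[i], x$fdr$fdr_percent[i],
                  x$fdr$n_false[i], x$fdr$n_from[i]))
    }
  }
  print(x$metrics)
  invisible(x)
}
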