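# Muscle-synergy extraction: (concatenated) NMF with multiplicative
# updates, the VAF/MSE model-order criterion, cosine-similarity matching of
# spatial patterns, and fixed-W temporal estimation by per-frame NNLS.

#' @noRd
act_matrix <- function(A) {
  if (is.data.frame(A)) {
    chans <- signals_channels(A)
    m <- t(as.matrix(A[chans]))
    rownames(m) <- chans
    m
  } else if (is.matrix(A)) {
    A
  } else {
    abort("`A` must be a tibble (time x channels) or a muscles x time matrix")
  }
}

#' Variance accounted for (VAF)
#'
#' Global, uncentered reconstruction quality of a synergy factorization:
#' `100 * (1 - ||A - W H||_F^2 / ||A||_F^2)`.
#'
#' @param A Activation data: tibble with `time_s` plus channel columns, or a
#'   muscles x time matrix.
#' @param W Spatial patterns (muscles x n).
#' @param H Temporal patterns (n x time).
#' @return VAF in percent (at most 100).
#' @export
vaf <- function(A, W, H) {
  A <- act_matrix(A)
  denom <- sum(A^2)
  if (denom == 0) abort("VAF is undefined for an all-zero activation matrix")
  100 * (1 - sum((A - W %*% H)^2) / denom)
}

#' Mean squared reconstruction error
#'
#' Mean over all muscles and frames of the squared residual `A - W H`.
#' Meaningful as an absolute threshold only on a fixed activation scale
#' (activations here are per-muscle max-normalized by [emg_envelope()]).
#'
#' @inheritParams vaf
#' @return Mean squared error (a single number).
#' @export
recon_mse <- function(A, W, H) {
  A <- act_matrix(A)
  if (length(A) == 0) abort("empty activation matrix")
  mean((A - W %*% H)^2)
}

#' Cosine similarity between two spatial patterns
#'
#' @param w1,w2 Non-zero numeric vectors of equal length.
#' @return `dot(w1, w2) / (||w1|| ||w2||)`; lies in \[0, 1\] for
#'   non-negative patterns.
#' @export
cosine_similarity <- function(w1, w2) {
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) abort("cosine similarity is undefined for a zero vector")
  sum(w1 * w2) / (n1 * n2)
}

#' @noRd
nmf_mu <- function(A, n, max_iter, tol, eps = 1e-12) {
  K <- nrow(A); T_ <- ncol(A)
  scale <- sqrt(mean(A) / n + eps)
  W <- matrix(runif(K * n), K, n) * scale
  H <- matrix(runif(n * T_), n, T_) * scale
  res_prev <- Inf
  it <- max_iter
  for (i in seq_len(max_iter)) {
    H <- H * crossprod(W, A) / (crossprod(W) %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (i %% 10 == 0 || i == max_iter) {
      res <- sqrt(sum((A - W %*% H)^2))
      if (is.finite(res_prev) &&
          abs(res_prev - res) <= tol * max(res_prev, eps)) {
        it <- i
        break
      }
      res_prev <- res
      it <- i
    }
  }
  list(W = W, H = H, residual = sqrt(sum((A - W %*% H)^2)), iterations = it)
}

#' Fit non-negative matrix factorization to muscle activations
#'
#' Factorizes non-negative activations `A ~ W H` (spatial patterns `W`,
#' temporal patterns `H`) by multiplicative updates minimizing the Frobenius
#' residual, keeping the best of `restarts` random non-negative
#' initializations. Columns of `W` are max-normalized to 1 (the scale is
#' absorbed into `H`, resolving the factorization's scale indeterminacy) and
#' ordered by the peak time of their temporal pattern. Deterministic given
#' `seed`.
#'
#' @inheritParams vaf
#' @param n Number of synergies (1..K).
#' @param restarts Number of random restarts.
#' @param seed Integer seed.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative residual-change convergence tolerance.
#' @return Object of class `synergy_model`: list with `W`, `H`, `n`,
#'   `vaf_percent`, `mse`, `residual`, `iterations`, `restarts`, `seed`,
#'   `muscles`, `time_s` (if `A` carried one).
#' @export
fit_nmf <- function(A, n, restarts = 20, seed = 1, max_iter = 2000,
                    tol = 1e-6) {
  time_s <- if (is.data.frame(A)) A$time_s else NULL
  A <- act_matrix(A)
  K <- nrow(A)
  if (any(A < 0)) abort("activation matrix must be non-negative")
  if (n < 1 || n > K) abort(sprintf("`n` must lie in [1, %d]", K))
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_local_seed(seed + r - 1, nmf_mu(A, n, max_iter, tol))
    if (is.null(best) || fit$residual < best$residual) best <- fit
  }
  # normalize W columns (max = 1) and order synergies by temporal peak
  cmax <- apply(best$W, 2, max)
  cmax[cmax == 0] <- 1
  W <- sweep(best$W, 2, cmax, "/")
  H <- sweep(best$H, 1, cmax, "*")
  ord <- order(apply(H, 1, which.max))
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  colnames(W) <- paste0("Syn", seq_len(n))
  rownames(H) <- colnames(W)
  rownames(W) <- rownames(A)
  structure(list(
    W = W, H = H, n = n,
    vaf_percent = vaf(A, W, H), mse = recon_mse(A, W, H),
    residual = best$residual, iterations = best$iterations,
    restarts = restarts, seed = seed,
    muscles = rownames(A), time_s = time_s
  ), class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> n=%d synergies over %d muscles: VAF=%.2f%%, MSE=%.3g\n",
              x$n, length(x$muscles), x$vaf_percent, x$mse))
  invisible(x)
}

#' Concatenate activation matrices across trials
#'
#' Time-axis concatenation for concatenated NMF (CNMF): factorizing data
#' pooled over trials reduces the influence of trial-to-trial variability.
#' Trial boundaries are recorded so the concatenation can be undone.
#'
#' @param trials List of activation tibbles (`time_s` plus identical channel
#'   columns, equal sampling rate).
#' @return Single activation tibble with a continuous `time_s` axis;
#'   attribute `"boundaries"` holds the end row of each input trial.
#' @export
concat_trials <- function(trials) {
  stopifnot(is.list(trials), length(trials) >= 1)
  chans <- signals_channels(trials[[1]])
  fs <- infer_fs(trials[[1]]$time_s)
  for (tr in trials[-1]) {
    if (!identical(signals_channels(tr), chans)) {
      abort("all trials must share the same muscle channels")
    }
    if (abs(infer_fs(tr$time_s) - fs) > 0.01 * fs) {
      abort("all trials must share the same sampling rate")
    }
  }
  lens <- vapply(trials, nrow, integer(1))
  out <- dplyr::bind_rows(lapply(trials, function(tr) tr[chans]))
  out <- dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(sum(lens)) - 1) / fs), out)
  attr(out, "boundaries") <- cumsum(lens)
  attr(out, "fs") <- fs
  out
}

#' Split a concatenated activation matrix back into trials
#'
#' Inverse of [concat_trials()] using its recorded `"boundaries"` attribute.
#'
#' @param x Tibble produced by [concat_trials()].
#' @return List of activation tibbles with trial-local time axes.
#' @export
split_trials <- function(x) {
  b <- attr(x, "boundaries")
  if (is.null(b)) abort("`x` carries no trial boundaries")
  fs <- infer_fs(x$time_s)
  starts <- c(1L, head(b, -1) + 1L)
  purrr::map2(starts, b, function(s, e) {
    out <- x[s:e, ]
    out$time_s <- (seq_len(e - s + 1) - 1) / fs
    out
  })
}

#' Select the number of synergies by the VAF/MSE criterion
#'
#' Fits best-of-restarts NMF for each candidate order `n = 1..K` and returns
#' the smallest `n` whose reconstruction satisfies both `VAF >= vaf_min`
#' (percent) and `MSE <= mse_max`. If no order satisfies both, the number of
#' channels `K` is returned with `satisfied = FALSE`.
#'
#' @inheritParams fit_nmf
#' @param vaf_min Minimum VAF in percent (default 90).
#' @param mse_max Maximum mean squared error (default 1e-5).
#' @return Object of class `order_selection`: list with `n`, `satisfied`,
#'   `criteria` (tibble of n, vaf, mse per candidate order), `model` (the
#'   fitted `synergy_model` at the selected order) and the thresholds.
#' @export
select_order <- function(A, restarts = 5, seed = 1, vaf_min = 90,
                         mse_max = 1e-5, max_iter = 2000, tol = 1e-6) {
  Am <- act_matrix(A)
  K <- nrow(Am)
  fits <- vector("list", K)
  rows <- vector("list", K)
  n_sel <- NA_integer_
  for (n in seq_len(K)) {
    fit <- fit_nmf(A, n, restarts = restarts, seed = seed,
                   max_iter = max_iter, tol = tol)
    fits[[n]] <- fit
    rows[[n]] <- tibble::tibble(n = n, vaf = fit$vaf_percent, mse = fit$mse,
                                iterations = fit$iterations)
    if (is.na(n_sel) && fit$vaf_percent >= vaf_min && fit$mse <= mse_max) {
      n_sel <- n
    }
  }
  satisfied <- !is.na(n_sel)
  if (!satisfied) n_sel <- K
  structure(list(
    n = n_sel, satisfied = satisfied,
    criteria = dplyr::bind_rows(rows),
    model = fits[[n_sel]],
    vaf_min = vaf_min, mse_max = mse_max
  ), class = "order_selection")
}

#' @export
print.order_selection <- function(x, ...) {
  cat(sprintf("<order_selection> n=%d (%s: VAF>=%.0f%%, MSE<=%g)\n",
              x$n, if (x$satisfied) "criterion satisfied" else
                "criterion NOT satisfied, K returned",
              x$vaf_min, x$mse_max))
  print(x$criteria)
  invisible(x)
}

#' @noRd
kperms <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in kperms(v[-i], k - 1)) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

#' Match two sets of spatial synergy patterns
#'
#' Finds the one-to-one assignment between the columns of `Wa` and `Wb`
#' maximizing total cosine similarity (exhaustive search, feasible for up to
#' 8 synergies per side). Also reports, per column of `Wa`, its best
#' (maximum-similarity) match in `Wb` regardless of the assignment.
#'
#' @param Wa,Wb Spatial pattern matrices with the same number of muscle
#'   rows; columns are synergies.
#' @return Object of class `synergy_match`: `assignment` tibble (`a`, `b`,
#'   `similarity`), `total` similarity, `best` tibble of per-column maxima,
#'   and the full `similarity` matrix.
#' @export
match_synergies <- function(Wa, Wb) {
  if (nrow(Wa) != nrow(Wb)) abort("`Wa` and `Wb` must have the same muscle rows")
  na <- ncol(Wa); nb <- ncol(Wb)
  if (is.null(colnames(Wa))) colnames(Wa) <- paste0("a", seq_len(na))
  if (is.null(colnames(Wb))) colnames(Wb) <- paste0("b", seq_len(nb))
  S <- matrix(0, na, nb, dimnames = list(colnames(Wa), colnames(Wb)))
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) S[i, j] <- cosine_similarity(Wa[, i], Wb[, j])
  }
  swap <- na > nb
  M <- if (swap) t(S) else S  # rows = smaller side
  k <- nrow(M)
  best_perm <- NULL; best_total <- -Inf
  for (p in kperms(seq_len(ncol(M)), k)) {
    tot <- sum(M[cbind(seq_len(k), p)])
    if (tot > best_total) {
      best_total <- tot
      best_perm <- p
    }
  }
  if (swap) {
    assignment <- tibble::tibble(a = colnames(Wa)[best_perm],
                                 b = colnames(Wb),
                                 similarity = M[cbind(seq_len(k), best_perm)])
  } else {
    assignment <- tibble::tibble(a = colnames(Wa),
                                 b = colnames(Wb)[best_perm],
                                 similarity = S[cbind(seq_len(k), best_perm)])
  }
  best <- tibble::tibble(
    a = colnames(Wa),
    b = colnames(Wb)[apply(S, 1, which.max)],
    similarity = apply(S, 1, max)
  )
  structure(list(assignment = assignment, total = best_total,
                 best = best, similarity = S),
            class = "synergy_match")
}

#' @export
print.synergy_match <- function(x, ...) {
  cat(sprintf("<synergy_match> total similarity %.3f\n", x$total))
  print(x$assignment)
  invisible(x)
}

#' Estimate temporal patterns under fixed spatial patterns
#'
#' Solves, frame by frame, the non-negative least-squares problem
#' `min ||a_t - W h_t||` with `h_t >= 0`, where `W` holds representative
#' spatial patterns (typically those fitted on training data). This is the
#' sequential, real-time-compatible route to temporal synergy activations:
#' each frame depends only on that frame's activation sample. A vectorized
#' unconstrained solve is used wherever it is already non-negative; the
#' remaining frames fall back to an active-set NNLS.
#'
#' @inheritParams vaf
#' @param W_fixed Muscles x n matrix of full column rank.
#' @return If `A` is a tibble, a tibble `time_s` plus one column per synergy;
#'   if a matrix, an n x time matrix.
#' @export
estimate_temporal <- function(A, W_fixed) {
  tib <- is.data.frame(A)
  time_s <- if (tib) A$time_s else NULL
  Am <- act_matrix(A)
  if (nrow(Am) != nrow(W_fixed)) abort("muscle dimensions of `A` and `W_fixed` differ")
  if (qr(W_fixed)$rank < ncol(W_fixed)) abort("`W_fixed` is rank-deficient")
  WtW <- crossprod(W_fixed)
  Hhat <- solve(WtW, crossprod(W_fixed, Am))
  neg <- which(apply(Hhat, 2, function(h) any(h < -1e-12)))
  for (j in neg) {
    Hhat[, j] <- pracma::lsqnonneg(W_fixed, Am[, j])$x
  }
  Hhat <- pmax(Hhat, 0)
  rownames(Hhat) <- colnames(W_fixed)
  if (tib) {
    out <- tibble::as_tibble(t(Hhat))
    dplyr::bind_cols(tibble::tibble(time_s = time_s), out)
  } else {
    Hhat
  }
}
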