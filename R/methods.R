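# broom-style tidy()/glance() methods and ggplot2 autoplot() methods for
# the package's result objects.

#' @export
tidy.synergy_model <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    muscle = rep(rownames(W), times = ncol(W)),
    synergy = rep(colnames(W), each = nrow(W)),
    weight = as.numeric(W)
  )
}

#' @export
glance.synergy_model <- function(x, ...) {
  tibble::tibble(n = x$n, vaf_percent = x$vaf_percent, mse = x$mse,
                 residual = x$residual, iterations = x$iterations,
                 restarts = x$restarts)
}

#' @export
tidy.order_selection <- function(x, ...) x$criteria

#' @export
glance.order_selection <- function(x, ...) {
  tibble::tibble(n = x$n, satisfied = x$satisfied,
                 vaf_min = x$vaf_min, mse_max = x$mse_max)
}

#' @export
tidy.synergy_match <- function(x, ...) x$assignment

#' @export
glance.synergy_match <- function(x, ...) {
  tibble::tibble(total = x$total, n_pairs = nrow(x$assignment),
                 mean_similarity = mean(x$assignment$similarity))
}

#' @export
tidy.sts_eval <- function(x, ...) x$metrics

#' @export
glance.sts_eval <- function(x, ...) {
  tibble::tibble(accuracy_percent = x$accuracy_percent,
                 timing_mean_ms = x$timing_mean_ms,
                 timing_sd_ms = x$timing_sd_ms,
                 timing_mean_abs_ms = x$timing_mean_abs_ms,
                 missed_transitions = x$misses, n = x$n)
}

#' @export
tidy.sts_forecaster <- function(x, ...) x$log

#' @export
glance.sts_forecaster <- function(x, ...) {
  tibble::tibble(best_val_accuracy = x$best_val_accuracy,
                 epochs = nrow(x$log), n_params = length(x$params),
                 classes = x$C, horizon_ms = x$config$horizon_ms)
}

#' @export
autoplot.synergy_model <- function(object, ...) {
  tidy(object) |>
    dplyr::mutate(muscle = factor(.data$muscle,
                                  levels = rev(object$muscles))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$weight, y = .data$muscle)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~synergy, nrow = 1) +
    ggplot2::labs(x = "muscle weight (max-normalized)", y = NULL,
                  title = sprintf("Spatial synergy patterns (VAF %.1f%%)",
                                  object$vaf_percent)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.order_selection <- function(object, ...) {
  d <- object$criteria |>
    tidyr::pivot_longer(c("vaf", "mse"), names_to = "criterion") |>
    dplyr::mutate(criterion = toupper(.data$criterion))
  thr <- tibble::tibble(criterion = c("VAF", "MSE"),
                        value = c(object$vaf_min, object$mse_max))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = object$n, linetype = "dotted") +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of synergies", y = NULL,
                  title = "Model-order criterion") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sts_eval <- function(object, ...) {
  pct <- object$confusion$percent
  d <- tibble::tibble(
    truth = factor(rep(rownames(pct), times = ncol(pct)),
                   levels = rev(object$classes)),
    pred = factor(rep(colnames(pct), each = nrow(pct)),
                  levels = object$classes),
    percent = as.numeric(pct)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pred, y = .data$truth,
                                  fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$percent), "",
                     sprintf("%.1f", .data$percent))), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 na.value = "grey90", limits = c(0, 100)) +
    ggplot2::labs(x = "predicted", y = "ground truth", fill = "%",
                  title = sprintf("Confusion matrix (accuracy %.1f%%)",
                                  object$accuracy_percent)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sts_trial <- function(object, muscles = NULL, ...) {
  env <- object$envelopes
  if (!is.null(muscles)) env <- env[c("time_s", muscles)]
  d <- tidyr::pivot_longer(env, -"time_s", names_to = "muscle",
                           values_to = "activation")
  hip <- object$markers |>
    dplyr::mutate(muscle = "hip height",
                  activation = .data$hip_height) |>
    dplyr::select("time_s", "muscle", "activation")
  dplyr::bind_rows(d, hip) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$time_s, y = .data$activation)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$muscle),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("Synthetic trial (%s strategy)",
                                  object$strategy)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sts_forecaster <- function(object, ...) {
  d <- tidyr::pivot_longer(object$log, c("loss", "val_accuracy"),
                           names_to = "measure")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Forecaster training") +
    ggplot2::theme_minimal()
}
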