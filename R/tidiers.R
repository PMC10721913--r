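#' Tidy a decoding timecourse
#'
#' @param x a `decoding_timecourse`.
#' @param ... unused.
#' @return long tibble with columns `time`, `repetition`, `accuracy`.
#' @exportS3Method generics::tidy
tidy.decoding_timecourse <- function(x, ...) {
  tibble(
    time = rep(x$times, each = nrow(x$accuracies)),
    repetition = rep(seq_len(nrow(x$accuracies)), times = ncol(x$accuracies)),
    accuracy = as.vector(x$accuracies)
  )
}

#' @exportS3Method generics::glance
glance.decoding_timecourse <- function(x, ...) {
  m <- colMeans(x$accuracies)
  tibble(
    target = x$pair$target, control = x$pair$control,
    test_condition = x$test_condition, kind = x$kind,
    k = x$k, n_repetitions = nrow(x$accuracies),
    n_times = ncol(x$accuracies), chance = x$chance,
    mean_accuracy = mean(m),
    peak_accuracy = max(m), peak_time = x$times[which.max(m)]
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.decoding_timecourse <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(mean = mean(.data$accuracy),
                     se = sd(.data$accuracy) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$chance, linetype = "dashed") +
    ggplot2::labs(x = "Time (ms)", y = "Decoding accuracy",
                  title = paste0(format(object$pair),
                                 if (!is.na(object$test_condition))
                                   paste0(" → ", object$test_condition)
                                 else "")) +
    ggplot2::theme_minimal()
}

#' Tidy a temporal generalization matrix
#'
#' @param x a `tg_matrix`.
#' @param ... unused.
#' @return tibble with columns `train_time`, `test_time`, `score`.
#' @exportS3Method generics::tidy
tidy.tg_matrix <- function(x, ...) {
  tibble(
    train_time = rep(x$times, times = length(x$times)),
    test_time = rep(x$times, each = length(x$times)),
    score = as.vector(x$values)
  )
}

#' @exportS3Method generics::glance
glance.tg_matrix <- function(x, ...) {
  d <- diag(x$values)
  tibble(
    target = x$train_pair$target, control = x$train_pair$control,
    test_condition = x$test_condition,
    n_times = length(x$times),
    diag_peak = max(d), diag_peak_time = x$times[which.max(d)],
    offdiag_max = max(x$values)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.tg_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$test_time, y = .data$train_time,
                               fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "navy",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "Test time (ms)", y = "Train time (ms)",
                  fill = "Score",
                  title = sprintf("TG: train %s, test %s",
                                  format(object$train_pair),
                                  object$test_condition)) +
    ggplot2::theme_minimal()
}

#' Tidy a z-map
#'
#' @param x a `zmap`.
#' @param ... unused.
#' @return tibble with `time` (or `train_time`/`test_time`), `z`,
#'   `significant` and, when available, `accuracy`.
#' @exportS3Method generics::tidy
tidy.zmap <- function(x, ...) {
  if (is.null(dim(x$z))) {
    tibble(
      time = x$times, z = as.vector(x$z),
      significant = as.vector(x$mask),
      accuracy = if (is.null(x$accuracy)) NA_real_ else as.vector(x$accuracy)
    )
  } else {
    tibble(
      train_time = rep(x$times, times = ncol(x$z)),
      test_time = rep(x$times, each = nrow(x$z)),
      z = as.vector(x$z),
      significant = as.vector(x$mask),
      accuracy = if (is.null(x$accuracy)) NA_real_ else as.vector(x$accuracy)
    )
  }
}

#' @exportS3Method generics::glance
glance.zmap <- function(x, ...) {
  tibble(
    analysis = x$analysis, z_crit = x$z_crit,
    n_points = length(x$z), n_significant = sum(x$mask),
    n_clusters = nrow(x$clusters),
    max_abs_z = max(abs(x$z)),
    n_repetitions = length(x$per_rep_z %||% list(NULL))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.zmap <- function(object, ...) {
  df <- tidy(object)
  if (is.null(dim(object$z))) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$z)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                          colour = "goldenrod", size = 1.6) +
      ggplot2::geom_hline(yintercept = c(-object$z_crit, object$z_crit),
                          linetype = "dashed") +
      ggplot2::labs(x = "Time (ms)", y = "z", title = object$analysis) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$test_time,
                                     y = .data$train_time, fill = .data$z)) +
      ggplot2::geom_raster() +
      ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                          colour = "goldenrod", size = 0.3) +
      ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                    high = "firebrick") +
      ggplot2::labs(x = "Test time (ms)", y = "Train time (ms)",
                    title = object$analysis) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom rlang .data
NULL
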