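#' Plot a confusion matrix heatmap for a chaos evaluation
#'
#' @param object A `chaos_eval` from [global_metrics()].
#' @param normalise Show row-normalised rates instead of counts
#'   (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaos_eval <- function(object, normalise = TRUE, ...) {
  df <- as.data.frame(object$confusion)
  names(df) <- c("truth", "prediction", "count")
  if (normalise) {
    df <- df |>
      dplyr::group_by(.data$truth) |>
      dplyr::mutate(value = ifelse(sum(.data$count) > 0,
                                   .data$count / sum(.data$count), 0)) |>
      dplyr::ungroup()
    lab <- "rate"
  } else {
    df$value <- df$count
    lab <- "count"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 2)),
                       colour = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted chaos level", y = "True chaos level",
                  fill = lab) +
    ggplot2::theme_minimal()
}

#' Plot ablation performance against training-set size
#'
#' @param object A `chaos_ablation` tibble from [run_ablation()].
#' @param metric Column to plot (default `"macro_f1"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chaos_ablation <- function(object, metric = "macro_f1", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size_hours,
                                       y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "Balanced training data (hours, log2)", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a log-mel patch
#'
#' @param patch A 96 x 101 log-mel matrix from [logmel_patches()].
#' @return A ggplot object.
#' @export
plot_logmel <- function(patch) {
  df <- expand.grid(band = seq_len(nrow(patch)), frame = seq_len(ncol(patch)))
  df$value <- as.numeric(patch)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$band,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Frame (20 ms hop)", y = "Mel band",
                  fill = "log power") +
    ggplot2::theme_minimal()
}
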