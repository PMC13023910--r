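#' Plot current-time traces
#'
#' @param traces Long trace tibble (`sample_id`, `time_s`, `current_mA`).
#' @param injection_time Injection time (s), drawn as a dashed rule.
#' @param colour_by Optional metadata tibble (`sample_id` plus one column)
#'   used to colour traces, e.g. EC level.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, injection_time = 60, colour_by = NULL) {
  dat <- traces
  mapping <- ggplot2::aes(x = .data$time_s, y = .data$current_mA,
                          group = .data$sample_id)
  if (!is.null(colour_by)) {
    col <- setdiff(names(colour_by), "sample_id")[1]
    dat <- dplyr::left_join(traces, colour_by, by = "sample_id")
    mapping <- ggplot2::aes(x = .data$time_s, y = .data$current_mA,
                            group = .data$sample_id,
                            colour = factor(.data[[col]]))
  }
  ggplot2::ggplot(dat, mapping) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = injection_time, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "current (mA)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot mectox_learning_curve
#' @export
autoplot.mectox_learning_curve <- function(object, ...) {
  d <- as_tibble(object)
  long <- dplyr::bind_rows(
    tibble(train_size = d$train_size, rmse = d$train_error,
           sd = d$train_sd, set = "training"),
    tibble(train_size = d$train_size, rmse = d$val_error,
           sd = d$val_sd, set = "validation")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$train_size, .data$rmse,
                                     colour = .data$set)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$rmse - .data$sd, ymax = .data$rmse + .data$sd,
                   fill = .data$set),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training samples", y = "RMSE (ppm)",
                  colour = NULL, fill = NULL,
                  title = paste0("Learning curve: ",
                                 attr(object, "target") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot per-toxicant Gini importances
#'
#' @param importance Tibble from [importance_table()].
#' @param top_n Features shown per toxicant.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 10) {
  dat <- importance |>
    group_by(.data$toxicant) |>
    dplyr::slice_min(.data$rank, n = top_n) |>
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(.data$importance,
                                    stats::reorder(.data$feature,
                                                   .data$importance))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~toxicant, scales = "free_y") +
    ggplot2::labs(x = "normalized Gini importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-true scatter for cross-validated models
#'
#' @param x A `mectox_cv` object or bound predictions tibble.
#' @return A ggplot object faceted by toxicant (and model if several).
#' @export
plot_predictions <- function(x) {
  preds <- if (inherits(x, "mectox_cv")) x$predictions else x
  ggplot2::ggplot(preds, ggplot2::aes(.data$y_true, .data$y_pred,
                                      colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~toxicant, scales = "free") +
    ggplot2::labs(x = "true concentration (ppm)",
                  y = "predicted concentration (ppm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
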