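# ggplot2 views of fits, prediction sets and benchmark results.

#' Plot the predicted-weight distributions of a fit
#'
#' Histogram of nonzero predicted weights per relation on a log10 x-axis, with
#' the reporting threshold `tau` marked. The heavy mass below the line is the
#' diffuse background the threshold is designed to cut away.
#'
#' @param object A `heterolp_fit` or `dthybrid_fit`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heterolp_fit <- function(object, bins = 40, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$weight > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight, fill = .data$novel)) +
    ggplot2::geom_histogram(bins = bins, position = "stack") +
    ggplot2::geom_vline(xintercept = object$config$tau, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~relation, scales = "free_y") +
    ggplot2::labs(x = "predicted weight (log scale)", y = "pairs",
                  fill = "novel",
                  title = "Predicted association weights",
                  subtitle = sprintf("dashed line: reporting threshold tau = %g",
                                     object$config$tau)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.heterolp_fit
#' @export
autoplot.dthybrid_fit <- autoplot.heterolp_fit

#' Plot a prediction set
#'
#' Ranked weights of the retained novel predictions, one panel per relation.
#'
#' @param object A `heterolp_predictions` tibble.
#' @param top_n Show at most this many top-ranked pairs per relation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heterolp_predictions <- function(object, top_n = 30, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$relation) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(pair = paste(.data$row_id, .data$col_id, sep = " - ")) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weight,
                                   y = stats::reorder(.data$pair, .data$weight))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~relation, scales = "free_y") +
    ggplot2::labs(x = "predicted weight", y = NULL,
                  title = sprintf("Novel predictions (weight >= %g)",
                                  attr(object, "tau"))) +
    ggplot2::theme_minimal()
}

#' Plot a hold-out benchmark
#'
#' AUC per replicate and method, with one point per seed.
#'
#' @param object A `holdout_eval` from [evaluate_holdout()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.holdout_eval <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "hold-out AUC",
                  title = sprintf("Link recovery on held-out %s associations",
                                  gsub("_", "-", attr(object, "relation")))) +
    ggplot2::theme_minimal()
}
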