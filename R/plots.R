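#' Plot clinical score trajectories
#'
#' Spaghetti plot of per-subject scale scores over the observation period,
#' optionally coloured by an outcome label.
#'
#' @param trajectories Trajectory tibble (`subject_id`, `diagnosis`,
#'   `scale`, `day`, `score`).
#' @param labels Optional labels tibble with `subject_id` and the column
#'   named in `colour`.
#' @param colour Label column used for colouring; default `"responder"`.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, labels = NULL,
                              colour = "responder", alpha = 0.3) {
  check_trajectory(trajectories)
  d <- trajectories
  if (!is.null(labels)) {
    d <- dplyr::left_join(d, labels[, c("subject_id", colour)], by = "subject_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$score,
                                       group = .data$subject_id))
  p <- if (!is.null(labels)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]), alpha = alpha)
  } else {
    p + ggplot2::geom_line(alpha = alpha)
  }
  p +
    ggplot2::facet_wrap(ggplot2::vars(.data$scale), scales = "free_y") +
    ggplot2::labs(x = "day", y = "score") +
    ggplot2::theme_minimal()
}

#' @describeIn diversity_summary Histogram of per-gene diversity indices.
#' @param object A `diversity_report`.
#' @param ... Unused.
#' @export
autoplot.diversity_report <- function(object, ...) {
  ggplot2::ggplot(object$per_gene, ggplot2::aes(x = .data$d)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_d, linetype = 2) +
    ggplot2::labs(x = "diversity index d", y = "genes") +
    ggplot2::theme_minimal()
}

#' @describeIn pattern_catalog Bar chart of pattern shares (descending).
#' @param object A `pattern_catalog`.
#' @param max_patterns Show at most this many patterns; default 20.
#' @param ... Unused.
#' @export
autoplot.pattern_catalog <- function(object, max_patterns = 20, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pattern) |>
    dplyr::slice_head(n = max_patterns) |>
    dplyr::mutate(pattern = factor(.data$pattern, levels = .data$pattern))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pattern, y = .data$count)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "genotypic pattern (gene-vector code)", y = "subjects",
      title = attr(object, "gene")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn kfold_cv Per-fold sensitivity and specificity.
#' @param object An `nn_cv`.
#' @param ... Unused.
#' @export
autoplot.nn_cv <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$folds[, c("fold", "sensitivity", "specificity")],
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$pooled$sensitivity, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fold", y = "test-fold rate") +
    ggplot2::theme_minimal()
}
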