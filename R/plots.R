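#' @describeIn similarity Heatmap of the cross-dataset similarity matrix;
#'   a bright diagonal against a dim background is the visual signature of
#'   a differentiable cohort.
#' @param object A `similarity_matrix`.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  df <- tidy(object)
  df$subject_1 <- factor(df$subject_1, levels = object$subject_ids)
  df$subject_2 <- factor(df$subject_2, levels = object$subject_ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$subject_2, .data$subject_1,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(
      x = paste0("dataset 2 (", object$dataset_pair[2], ")"),
      y = paste0("dataset 1 (", object$dataset_pair[1], ")"),
      fill = "Pearson r",
      title = "Cohort similarity matrix") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @describeIn run_challenge Accuracy per dataset pair and probe direction.
#' @param object A `challenge_result`.
#' @export
autoplot.challenge_result <- function(object, ...) {
  df <- object$accuracies
  df$pair <- paste(df$dataset_1, "vs", df$dataset_2)
  ggplot2::ggplot(df, ggplot2::aes(.data$pair, .data$accuracy,
                                   shape = .data$direction)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = 1 / object$n_subjects,
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "differentiation accuracy",
                  title = sprintf("%s challenge, %s features (%s)",
                                  object$challenge, object$type,
                                  object$band),
                  caption = "dashed line: chance level 1/N") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn pls_fit Bootstrap ratios of the strongest neural saliences
#'   for one latent variable (requires [pls_bootstrap()]).
#' @param object A `pls_result`.
#' @param lv Latent variable to plot (default 1).
#' @param top_n Number of features shown (default 20).
#' @export
autoplot.pls_result <- function(object, lv = 1, top_n = 20, ...) {
  if (is.null(object$bootstrap_ratio)) {
    abort("Run pls_bootstrap() before plotting bootstrap ratios.")
  }
  df <- tibble(
    feature = object$y_labels,
    ratio = object$bootstrap_ratio[, lv]
  )
  df <- dplyr::slice_max(df, abs(.data$ratio), n = top_n)
  df$feature <- stats::reorder(df$feature, df$ratio)
  ggplot2::ggplot(df, ggplot2::aes(.data$ratio, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::labs(x = sprintf("bootstrap ratio (LV %d)", lv), y = NULL,
                  title = "PLS neural saliences: bootstrap stability",
                  caption = "dashed lines: |ratio| = 2") +
    ggplot2::theme_minimal()
}

#' Differentiability score plot
#'
#' Dot plot of per-participant differentiability, ordered by score, with
#' the z = 0 reference line.
#'
#' @param scores Output of [differentiability()].
#' @return A ggplot object.
#' @export
plot_differentiability <- function(scores) {
  df <- dplyr::arrange(scores, .data$d_self)
  df$subject_id <- factor(df$subject_id, levels = df$subject_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$d_self, .data$subject_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "differentiability (z)", y = NULL,
                  title = "Per-participant differentiability") +
    ggplot2::theme_minimal()
}
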