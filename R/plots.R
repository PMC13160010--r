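# ggplot2 visualizations for the main result objects

#' Plot cursor trajectories of a session
#'
#' One path per phase record, colored by success, with the target ring
#' and target positions overlaid.
#'
#' @param object A [generate_session()] session.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bci_session <- function(object, ...) {
  b <- dplyr::left_join(object$bins,
                        dplyr::select(object$trials, "trial_id", "success",
                                      "phase"),
                        by = "trial_id")
  tg <- dplyr::distinct(object$trials, .data$target_x, .data$target_y)
  ggplot2::ggplot(b, ggplot2::aes(.data$cursor_x, .data$cursor_y,
                                  group = .data$trial_id,
                                  color = .data$success)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_point(data = tg,
                        ggplot2::aes(.data$target_x, .data$target_y),
                        inherit.aes = FALSE, shape = 1, size = 4) +
    ggplot2::coord_equal(xlim = c(-1, 1), ylim = c(-1, 1)) +
    ggplot2::labs(x = "x (screen units)", y = "y (screen units)",
                  color = "success") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation accuracy against chance
#'
#' @param object A [cross_validate_time()] / [cross_validate_targets()]
#'   result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bci_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(factor(.data$fold),
                                             .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$chance, linetype = 2) +
    ggplot2::labs(x = "fold", y = "held-out accuracy",
                  subtitle = sprintf("overall %.3f, greedy chance %.3f",
                                     object$accuracy, object$chance)) +
    ggplot2::theme_minimal()
}

#' Plot an epoch-comparison report
#'
#' Faceted view of the per-epoch statistics and pairwise alignment indices
#' (with chance intervals) from [compare_epochs()].
#'
#' @param report A [compare_epochs()] tibble.
#' @return A ggplot object.
#' @export
plot_epoch_comparison <- function(report) {
  per_epoch <- dplyr::filter(report, !is.na(.data$epoch))
  per_epoch$epoch <- factor(per_epoch$epoch,
                            c("correct", "pre_error", "error"))
  ggplot2::ggplot(per_epoch, ggplot2::aes(.data$epoch, .data$value,
                                          fill = .data$epoch)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~.data$statistic, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an LDA projection of labeled epochs
#'
#' @param lda A [lda_project()] result.
#' @return A ggplot object.
#' @export
plot_lda_projection <- function(lda) {
  df <- tibble(ld1 = lda$projection[, 1], ld2 = lda$projection[, 2],
               label = lda$labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$ld1, .data$ld2,
                                   color = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "LD1", y = "LD2", color = "epoch") +
    ggplot2::theme_minimal()
}
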