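# ggplot2 visualisations for the result objects.

#' @export
autoplot.pli_matrix <- function(object, ...) {
  td <- tidy(object)
  td <- dplyr::bind_rows(
    td,
    dplyr::rename(td, chan_1 = "chan_2", chan_2 = "chan_1")
  )
  labs <- object$channel_labels
  td$chan_1 <- factor(td$chan_1, levels = labs)
  td$chan_2 <- factor(td$chan_2, levels = rev(labs))
  ggplot2::ggplot(td, ggplot2::aes(.data$chan_1, .data$chan_2, fill = .data$pli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLI") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("%s band (%g-%g Hz) phase lag index",
                      object$band$name, object$band$low, object$band$high)
    ) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.classifier_report <- function(object, ...) {
  auc <- object$metrics$auc
  ggplot2::ggplot(object$roc_points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC, pooled cross-validated predictions (AUC = %.3f)", auc)
    ) +
    ggplot2::theme_minimal()
}

#' Group comparison of global PLI per band
#'
#' Bar-and-error plot of the per-band global PLI by group, with the rank-sum
#' p-values from [global_band_comparison()].
#'
#' @param conn connectivity tibble from [cohort_connectivity()].
#' @param cohort cohort tibble with `subject_id` and `group`.
#' @return a ggplot object.
#' @export
plot_global_pli <- function(conn, cohort) {
  d <- conn |>
    dplyr::inner_join(dplyr::select(cohort, "subject_id", "group"),
                      by = "subject_id") |>
    dplyr::group_by(.data$band, .data$group) |>
    dplyr::summarise(
      mean = mean(.data$global_pli), sd = sd(.data$global_pli),
      .groups = "drop"
    )
  d$band <- factor(d$band, levels = eeg_bands()$name)
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = "Frequency band", y = "Global PLI", fill = NULL) +
    ggplot2::theme_minimal()
}

#' MoCA versus global alpha PLI scatter plot per group
#'
#' @inheritParams plot_global_pli
#' @export
plot_moca_correlation <- function(conn, cohort) {
  d <- conn |>
    dplyr::filter(.data$band == "alpha") |>
    dplyr::inner_join(cohort, by = "subject_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$global_pli, .data$moca, colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Global alpha PLI", y = "MoCA score", colour = NULL) +
    ggplot2::theme_minimal()
}
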