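#' @export
autoplot.coab_density_scan <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$threshold,
                                             y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected, linetype = "dashed") +
    ggplot2::labs(x = "correlation threshold", y = "network density",
                  title = "Density sensitivity scan") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coab_evaluation <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$roc$ppi, variant = "PPI"),
    dplyr::mutate(object$roc$ppi_plus_coa, variant = "PPI + CoA")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                  colour = .data$variant)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "Cross-validated ROC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coab_ratio_scan <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$ratio,
                                             y = .data$mean_auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_ratio,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "co-abundance / PPI weight ratio",
                  y = "mean cross-validated AUROC") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coab_proximity <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::transmute(object$hist_obs, length = .data$length,
                     count = .data$count, which = "observed"),
    dplyr::transmute(object$hist_null, length = .data$length,
                     count = .data$mean_count, which = "degree-matched null")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$count,
                                  fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "shortest path length (hops)",
                  y = "candidate-target pairs",
                  title = sprintf("D = %.2f, z = %.2f, p_emp = %.3g",
                                  object$D, object$z, object$p_emp)) +
    ggplot2::theme_minimal()
}
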