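#' Plot experiment metrics
#'
#' Bar chart of Acc/Sn/Sp/MCC per results row, faceted by metric.
#'
#' @param object A `promoter_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.promoter_results <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("species_test", "model", "Acc", "Sn", "Sp",
                                 "MCC")],
    cols = c("Acc", "Sn", "Sp", "MCC"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$species_test,
                                     y = .data$value,
                                     fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-species accuracy matrix
#'
#' Heatmap of test accuracy for every (training species, test species) pair;
#' the diagonal holds the within-species held-out accuracy.
#'
#' @param object A `cross_species_results` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_species_results <- function(object, ...) {
  d <- dplyr::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species_test,
                                  y = .data$species_train,
                                  fill = .data$Acc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$Acc))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "tested on", y = "trained on", fill = "Acc") +
    ggplot2::theme_minimal()
}

#' Plot a model's training history
#'
#' @param object A trained neural `promoter_model`.
#' @param ... Unused.
#' @return A ggplot object of per-epoch training and validation loss.
#' @export
autoplot.promoter_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, cols = c("loss", "val_loss"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
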