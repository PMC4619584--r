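#' Plot a null-model test as a histogram with the observed value
#'
#' @param object a [null_test()] object.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.null_test <- function(object, ...) {
  df <- tidy.null_test(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic_name, y = "null replicates",
      title = sprintf("%s vs %s null: observed %.3g, null %.3g ± %.2g",
                      object$statistic_name, object$model, object$observed,
                      object$null_mean, object$null_sd)) +
    ggplot2::theme_minimal()
}

#' Plot a secondary-extinction curve
#'
#' @param object a [random_robustness()] object.
#' @param ... unused.
#' @return a ggplot of the mean survivors-vs-removed curve.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.robustness <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$removed_frac,
                               y = .data$surviving_frac)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_area(alpha = 0.2, fill = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = paste("fraction of", object$removal_level, "removed"),
                  y = "fraction surviving (other level)",
                  title = sprintf("Robustness R = %.3f", object$R)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a consumption matrix
#'
#' @param object a [consumption_matrix()].
#' @param ... unused.
#' @return a ggplot tile map (log1p fill).
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.consumption_matrix <- function(object, ...) {
  df <- tidy.consumption_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frugivore, y = .data$plant,
                                   fill = log1p(.data$weight))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log(1 + w)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Bar chart of NRI/NTI assemblage classifications
#'
#' @param result an [ensemble_indices()] tibble.
#' @return a ggplot comparing class frequencies under NRI and NTI.
#' @export
plot_assemblage_classes <- function(result) {
  long <- tidyr::pivot_longer(result, c("class_nri", "class_nti"),
                              names_to = "index", values_to = "class")
  long$index <- toupper(sub("class_", "", long$index))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, fill = .data$index)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "phylogenetic pattern", y = "species") +
    ggplot2::theme_minimal()
}
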