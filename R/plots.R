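#' Plot per-seed mean spectra
#'
#' Spaghetti plot of the `wl_*` columns of a spectra table, coloured by
#' class label.
#'
#' @param table Spectra tibble.
#' @param colour Metadata column to colour by (default `label`).
#' @return A ggplot object.
#' @export
plot_spectra <- function(table, colour = "label") {
  long <- table %>%
    mutate(.row = dplyr::row_number()) %>%
    tidyr::pivot_longer(dplyr::starts_with("wl_"),
                        names_to = "band", values_to = "value") %>%
    mutate(wavelength = parse_band_names(.data$band))
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$value,
                                     group = .data$.row,
                                     colour = factor(.data[[colour]]))) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "wavelength (nm)", y = "value", colour = colour) +
    ggplot2::theme_minimal()
}

#' @describeIn tidy.plsda_model Coefficient-curve plot: regression
#'   coefficient against wavelength with the `|b|` peaks marked.
#' @param object A `"plsda_model"`.
#' @export
autoplot.plsda_model <- function(object, ...) {
  td <- tidy(object)
  peaks <- td %>% filter(.data$is_peak) %>%
    arrange(dplyr::desc(abs(.data$coefficient))) %>% head(3)
  ggplot2::ggplot(td, ggplot2::aes(.data$wavelength, .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = peaks, colour = "red") +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient b") +
    ggplot2::theme_minimal()
}

#' Heat-map plot of a chemical image
#'
#' @param object A `"chemical_image"`.
#' @param ... Unused.
#' @return A ggplot object (prediction map; background pixels blank).
#' @export
autoplot.chemical_image <- function(object, ...) {
  d <- dim(object$prediction)
  df <- tibble::tibble(
    line = rep(seq_len(d[1]), d[2]),
    pixel = rep(seq_len(d[2]), each = d[1]),
    score = as.vector(object$prediction))
  ggplot2::ggplot(df, ggplot2::aes(.data$pixel, .data$line, fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "grey20", high = "red", na.value = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "pixel", y = "scan line", fill = "score") +
    ggplot2::theme_minimal()
}

#' Cross-validation error curve of a fitted model
#'
#' @param model A `"plsda_model"` with a stored CV curve.
#' @return A ggplot object: misclassification error against latent-variable
#'   count, the selected count marked.
#' @export
plot_cv_curve <- function(model) {
  if (is.null(model$cv)) abort("model carries no CV curve", class = "hsisort_error_model")
  ggplot2::ggplot(model$cv, ggplot2::aes(.data$lv, .data$error)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = model$n_lv, linetype = 2, colour = "red") +
    ggplot2::labs(x = "latent variables", y = "CV misclassification error") +
    ggplot2::theme_minimal()
}

#' Error-bar plot for a group-difference report
#'
#' @param report Tibble from [group_difference_report()].
#' @return A ggplot object: per-variety group means with +/- sd bars.
#' @export
plot_group_difference <- function(report) {
  long <- report %>%
    select("variety", "analyte", "mean_viable", "sd_viable",
           "mean_nonviable", "sd_nonviable") %>%
    tidyr::pivot_longer(-c("variety", "analyte"),
                        names_to = c(".value", "group"),
                        names_pattern = "(mean|sd)_(.*)")
  ggplot2::ggplot(long, ggplot2::aes(.data$variety, .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.9), width = 0.2) +
    ggplot2::labs(y = report$analyte[[1]], x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
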