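#' Plot a force-distance cycle
#'
#' Approach and retract force against piezo z-displacement, the standard way
#' force spectroscopy traces are displayed.
#'
#' @param curve One-curve tibble (`z_nm`, `f_approach_pN`, `f_retract_pN`).
#' @return A ggplot.
#' @export
plot_force_curve <- function(curve) {
  long <- tidyr::pivot_longer(
    curve, dplyr::all_of(c("f_approach_pN", "f_retract_pN")),
    names_to = "segment", values_to = "force_pN"
  )
  long$segment <- ifelse(long$segment == "f_approach_pN", "approach",
                         "retract")
  ggplot2::ggplot(long, ggplot2::aes(.data$z_nm, .data$force_pN,
                                     colour = .data$segment)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "piezo z-displacement (nm)", y = "force (pN)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_double_gaussian Histogram with the fitted components and
#'   their sum overlaid.
#' @param object A `"double_gaussian_fit"`.
#' @param ... Unused.
#' @export
autoplot.double_gaussian_fit <- function(object, ...) {
  pred <- predict(object)
  pred_long <- tidyr::pivot_longer(
    pred, dplyr::all_of(c("count_component1", "count_component2",
                          "count_total")),
    names_to = "curve", values_to = "count"
  )
  ggplot2::ggplot() +
    ggplot2::geom_col(
      data = object$histogram,
      ggplot2::aes(.data$center_pN, .data$count),
      width = object$bin_width, fill = "grey80", colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = pred_long,
      ggplot2::aes(.data$force_pN, .data$count, colour = .data$curve,
                   linetype = .data$curve)
    ) +
    ggplot2::scale_colour_manual(
      values = c(count_component1 = "#1b9e77", count_component2 = "#d95f02",
                 count_total = "black"),
      labels = c("component 1", "component 2", "sum"), name = NULL
    ) +
    ggplot2::scale_linetype_manual(
      values = c(count_component1 = "dashed", count_component2 = "dashed",
                 count_total = "solid"),
      labels = c("component 1", "component 2", "sum"), name = NULL
    ) +
    ggplot2::labs(x = "rupture force (pN)", y = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_topograph Height map as a raster image.
#' @param object A `"topograph"`.
#' @param ... Unused.
#' @export
autoplot.topograph <- function(object, ...) {
  px <- attr(object, "pixel_size_nm")
  df <- tibble::tibble(
    x_nm = (as.numeric(col(object)) - 0.5) * px,
    y_nm = (as.numeric(row(object)) - 0.5) * px,
    height_nm = as.numeric(object)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_nm, .data$y_nm,
                                   fill = .data$height_nm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "magma", name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}
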