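#' Plot flower density per diameter class and crown section
#'
#' Column chart of flowers per centimetre of shoot in each diameter class,
#' faceted by crown stratum and filled by crown layer.
#'
#' @param density A tibble from [flowers_per_cm_summary()].
#' @return A ggplot object.
#' @export
plot_flower_density <- function(density) {
  density |>
    dplyr::mutate(class = paste0(.data$class_lower_mm, "-", .data$class_upper_mm)) |>
    ggplot2::ggplot(ggplot2::aes(
      x = stats::reorder(.data$class, .data$class_lower_mm),
      y = .data$flowers_per_cm, fill = .data$layer
    )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(
      x = "branch diameter class (mm)", y = "flowers per cm shoot",
      fill = "crown layer"
    ) +
    ggplot2::theme_minimal()
}

#' Effect plot of the branch-level hurdle model
#'
#' Occurrence probability and expected flower number against branch diameter
#' for a set of dbh values, at the reference crown position (outer layer,
#' bottom stratum).
#'
#' @param object A [fit_flower_hurdle()] fit or [hurdle_coefficients()].
#' @param dbh_cm dbh values to draw curves for.
#' @param d_range Branch-diameter range, mm.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flower_hurdle <- function(object, dbh_cm = c(10, 20, 30),
                                   d_range = c(2, 30), ...) {
  autoplot(object$coefficients, dbh_cm = dbh_cm, d_range = d_range)
}

#' @rdname autoplot.flower_hurdle
#' @export
autoplot.hurdle_coefficients <- function(object, dbh_cm = c(10, 20, 30),
                                         d_range = c(2, 30), ...) {
  grid <- tidyr::expand_grid(
    D_mm = seq(d_range[1], d_range[2], length.out = 100),
    dbh = dbh_cm
  ) |>
    dplyr::mutate(
      `occurrence probability` = predict_occurrence_probability(
        .data$D_mm, .data$dbh, "out", "bot", object
      ),
      `flowers if flowering` = predict_conditional_count(
        .data$D_mm, .data$dbh, "out", "bot", object
      )
    ) |>
    tidyr::pivot_longer(-c("D_mm", "dbh"))
  ggplot2::ggplot(grid, ggplot2::aes(.data$D_mm, .data$value,
    colour = factor(.data$dbh)
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = "branch diameter (mm)", y = NULL, colour = "dbh (cm)") +
    ggplot2::theme_minimal()
}

#' Plot a tree-level allometry over its data
#'
#' @param object A fitted [tree_flower_model()].
#' @param data Optional per-tree table with the predictor column and flower
#'   totals to overlay as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tree_flower_model <- function(object, data = NULL, ...) {
  rng <- object$calibration_range %||% c(5, 30)
  xcol <- if (object$predictor == "dbh") "dbh_cm" else "crown_volume_m3"
  curve <- tibble::tibble(x = seq(rng[1], rng[2], length.out = 100)) |>
    dplyr::mutate(flowers = suppressWarnings(predict_tree_flowers(object, .data$x)))
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$x, .data$flowers)) +
    ggplot2::geom_line(colour = "tomato") +
    ggplot2::labs(
      x = if (object$predictor == "dbh") "dbh (cm)" else expression(crown ~ volume ~ (m^3)),
      y = "flowers per tree"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    pts <- tibble::tibble(
      x = data[[xcol]],
      flowers = data$median_total %||% data$flowers
    )
    p <- p + ggplot2::geom_point(data = pts, alpha = 0.7)
  }
  p
}

#' Plot resource budgets with confidence bands
#'
#' @param budget A tibble from [bootstrap_resource_ci()].
#' @return A ggplot object, one facet per quantity.
#' @export
plot_resource_budget <- function(budget) {
  ggplot2::ggplot(budget, ggplot2::aes(.data$dbh_cm, .data$estimate)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      alpha = 0.25, fill = "steelblue"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "dbh (cm)", y = NULL) +
    ggplot2::theme_minimal()
}
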