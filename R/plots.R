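# ggplot2 graphics for the main result types.

#' Histogram of sister-pair range overlap
#'
#' The overlap distribution with the complete-allopatry (< 0.05) and
#' complete-sympatry (> 0.95) bands shaded, the usual first look at a
#' sister-pair dataset.
#'
#' @param pairs A pair table with an `overlap_index` column.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_overlap_distribution <- function(pairs, bins = 20) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$overlap_index)) +
    ggplot2::annotate("rect",
      xmin = -Inf, xmax = 0.05, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "steelblue"
    ) +
    ggplot2::annotate("rect",
      xmin = 0.95, xmax = Inf, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "firebrick"
    ) +
    ggplot2::geom_histogram(
      bins = bins, boundary = 0, fill = "grey35", colour = "white"
    ) +
    ggplot2::labs(
      x = "range overlap (intersection / smaller range)",
      y = "sister pairs"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn arc_regression Scatter of overlap against branch length with
#'   the fitted age-range correlation back-transformed to the proportion
#'   scale.
#' @param object An `arc_fit`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot arc_fit
#' @export
autoplot.arc_fit <- function(object, ...) {
  d <- object$data
  co <- stats::coef(object$fit)
  grid <- tibble::tibble(
    branch_length_my = seq(0, max(d$branch_length_my), length.out = 100)
  )
  theta_hat <- pmin(pmax(co[1] + co[2] * grid$branch_length_my, 0), pi / 2)
  grid$overlap_index <- back_transform(theta_hat)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$branch_length_my, y = .data$overlap_index
  )) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "branch length (My since divergence)",
      y = "range overlap"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Median simulated indices across sympatric-speciation counts
#'
#' For each parameter combination, plots the median of the three summary
#' indices (completely sympatric count, completely allopatric count,
#' bimodality) against the number of sympatric speciation events, facetted
#' by index; observed values can be overlaid as dashed lines.
#'
#' @param object A [run_sweep()] result.
#' @param observed Optional one-row summary (`n`, `z`, `c`, `bimodality`)
#'   to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, observed = NULL, ...) {
  med <- object |>
    dplyr::group_by(
      .data$movement_sd, .data$movement_mean, .data$ancestral_fraction,
      .data$geometry, .data$n_sympatric
    ) |>
    dplyr::summarise(
      `completely sympatric` = stats::median(.data$z),
      `completely allopatric` = stats::median(.data$c),
      bimodality = stats::median(.data$bimodality),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(
      c("completely sympatric", "completely allopatric", "bimodality"),
      names_to = "index", values_to = "median"
    ) |>
    dplyr::mutate(
      cell = paste0(
        "sd=", .data$movement_sd, " mean=", .data$movement_mean,
        " frac=", .data$ancestral_fraction, " ", .data$geometry
      )
    )
  p <- ggplot2::ggplot(med, ggplot2::aes(
    x = .data$n_sympatric, y = .data$median,
    colour = .data$cell, group = .data$cell
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(
      x = "number of sympatric speciation events",
      y = "median of simulated index", colour = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
  if (!is.null(observed)) {
    obs <- tibble::tibble(
      index = c("completely sympatric", "completely allopatric", "bimodality"),
      value = c(observed$z, observed$c, observed$bimodality)
    )
    p <- p + ggplot2::geom_hline(
      data = obs, ggplot2::aes(yintercept = .data$value),
      linetype = "dashed", colour = "purple"
    )
  }
  p
}

#' Consistency map of a sympatric-fraction inference
#'
#' Tile plot of which (parameter combination, sympatric count) cells are
#' consistent with the observed data, per index and jointly.
#'
#' @param object A [consistent_sympatric_range()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sympatry_inference
#' @export
autoplot.sympatry_inference <- function(object, ...) {
  long <- object$cells |>
    dplyr::mutate(
      cell = paste0(
        "sd=", .data$movement_sd, " mean=", .data$movement_mean,
        " frac=", .data$ancestral_fraction, " ", .data$geometry
      )
    ) |>
    tidyr::pivot_longer(
      c("z_ok", "c_ok", "bimodality_ok", "joint_ok"),
      names_to = "index", values_to = "consistent"
    ) |>
    dplyr::mutate(index = sub("_ok$", "", .data$index))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$n_sympatric, y = .data$cell, fill = .data$consistent
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~index, ncol = 1) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "seagreen", `FALSE` = "grey85")
    ) +
    ggplot2::labs(
      x = "number of sympatric speciation events", y = NULL,
      fill = "consistent"
    ) +
    ggplot2::theme_minimal()
}
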