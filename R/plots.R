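#' Plot a fitted mixture over the width histogram
#'
#' Frequency histogram of the head-capsule widths with the fitted weighted
#' normal curves overlaid (scaled to counts) and, optionally, vertical
#' lines at the instar boundaries.
#'
#' @param object An `hcw_mixture` fitted on raw data.
#' @param bin_width Histogram bin width, micrometres, or `"auto"`.
#' @param boundaries Optional numeric vector (or tibble from
#'   [intersection_boundaries()]) of boundary positions to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcw_mixture <- function(object, bin_width = "auto",
                                 boundaries = NULL, ...) {
  if (length(object$x) == 0L) {
    stop("this model carries no raw data (imported from JSON?)",
         call. = FALSE)
  }
  d <- tibble::tibble(hcw_um = object$x)
  h <- make_histogram(d, bin_width = bin_width)
  bw <- attr(h, "bin_width")
  grid <- seq(min(object$x) - 3 * max(object$components$sd),
              max(object$x) + 3 * max(object$components$sd),
              length.out = 512)
  curves <- purrr::pmap_dfr(
    object$components,
    function(component, weight, mean, sd) {
      tibble::tibble(
        component = factor(component), hcw_um = grid,
        # weighted density scaled to expected bin counts
        count = object$n * bw * component_density(grid, weight, mean, sd)
      )
    })
  p <- ggplot2::ggplot() +
    ggplot2::geom_col(
      data = h,
      ggplot2::aes(x = .data$mid, y = .data$count),
      width = bw, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$hcw_um, y = .data$count,
                   colour = .data$component),
      linewidth = 0.8
    ) +
    ggplot2::labs(x = "Head-capsule width (µm)", y = "Frequency",
                  colour = "Instar") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    if (is.data.frame(boundaries)) boundaries <- boundaries$boundary_um
    p <- p + ggplot2::geom_vline(xintercept = boundaries,
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' Plot the Dyar's-rule regression
#'
#' Natural log of mean head-capsule width against instar number, with the
#' fitted least-squares line.
#'
#' @param object A `dyar_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dyar_regression <- function(object, ...) {
  df <- object$model$model
  ggplot2::ggplot(df, ggplot2::aes(x = .data$instar, y = .data$ln_mean)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Instar",
      y = "ln(mean head-capsule width, µm)",
      subtitle = sprintf("slope = %.4f, R² = %.3f", object$slope,
                         object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a complete instar analysis
#'
#' The mixture-over-histogram panel with instar boundaries marked.
#'
#' @param object An `instar_analysis`.
#' @param ... Passed to [autoplot.hcw_mixture()].
#' @return A ggplot object.
#' @export
autoplot.instar_analysis <- function(object, ...) {
  autoplot.hcw_mixture(object$model, boundaries = object$boundaries, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
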