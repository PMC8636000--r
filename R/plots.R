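#' Plot selection gradients by population, treatment and trait
#'
#' Bar chart of directional gradients with +/- 1 SE error bars, one facet
#' per trait, treatments side by side — the standard display for
#' across-population comparisons of herbivore-present versus
#' herbivore-exclusion selection.
#'
#' @param object A `florsel_gradients` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.florsel_gradients <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$population_id,
                                       y = .data$beta,
                                       fill = .data$treatment)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$beta - .data$se,
                   ymax = .data$beta + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~trait, ncol = 1) +
    ggplot2::labs(x = "population", y = "selection gradient β ± SE",
                  fill = "treatment") +
    ggplot2::theme_minimal()
}

#' Plot herbivore-mediated selection contrasts
#'
#' @param object A `florsel_mediated` tibble.
#' @param ... Unused.
#' @return A ggplot of `delta_beta` +/- SE per population, faceted by trait.
#' @export
autoplot.florsel_mediated <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$population_id,
                                       y = .data$delta_beta)) +
    ggplot2::geom_col(width = 0.7, fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$delta_beta - .data$se,
                   ymax = .data$delta_beta + .data$se),
      width = 0.25
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~trait, ncol = 1) +
    ggplot2::labs(x = "population",
                  y = "herbivore-mediated gradient Δβ ± SE") +
    ggplot2::theme_minimal()
}

#' Plot a meta-regression fit over its points
#'
#' Scatter of the across-population points (with +/- 1 SE bars where a
#' sampling SE is recorded) and the fitted linear or quadratic curve; the
#' vertex of a quadratic fit is marked with a dashed line.
#'
#' @param object A `florsel_meta_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.florsel_meta_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble::tibble(x = seq(min(pts$x), max(pts$x), length.out = 200))
  cf <- object$coefficients
  grid$y <- cf[1] + cf[2] * grid$x +
    if (object$degree == 2) cf[3] * grid$x^2 else 0
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point()
  if ("se" %in% names(pts) && any(pts$se > 0)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$se, ymax = .data$y + .data$se),
      width = 0
    )
  }
  p <- p + ggplot2::geom_line(data = grid, colour = "steelblue",
                              linewidth = 0.8)
  if (!is.na(object$vertex) &&
      object$vertex >= min(pts$x) && object$vertex <= max(pts$x)) {
    p <- p + ggplot2::geom_vline(xintercept = object$vertex,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = "herbivory intensity", y = "response",
                    subtitle = sprintf("%s %s fit, %s = %.2f", object$method,
                                       object$model, object$ic_type,
                                       object$ic)) +
    ggplot2::theme_minimal()
}
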