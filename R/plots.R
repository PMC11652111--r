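#' Plot the alpha-diversity profile of a mountain
#'
#' Species richness, Faith's PD and phylogenetic endemism against belt
#' midpoint elevation, free y-scales per index — the standard gradient
#' panel for one mountain.
#'
#' @param profile A [diversity_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_diversity_profile <- function(profile) {
  long <- tidyr::pivot_longer(
    dplyr::select(profile, "midpoint", "sr", "pd", "pe"),
    cols = c("sr", "pd", "pe"), names_to = "index", values_to = "value")
  long$index <- factor(long$index, levels = c("sr", "pd", "pe"),
                       labels = c("Species richness", "Faith's PD",
                                  "Phylogenetic endemism"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$midpoint, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "Belt midpoint elevation (m)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot adjacent-belt beta-diversity
#'
#' Jaccard similarity and Cody turnover between consecutive belts against
#' the elevation of the lower belt of each pair.
#'
#' @param beta An [adjacent_belt_profile()] tibble.
#' @param matrix Optional `belt_matrix` to recover belt midpoints for the
#'   x-axis; otherwise the belt index is used.
#' @return A ggplot object.
#' @export
plot_beta_profile <- function(beta, matrix = NULL) {
  x <- if (!is.null(matrix)) matrix$grid$midpoint[beta$belt_lo] else beta$belt_lo
  long <- tidyr::pivot_longer(
    dplyr::mutate(beta, x = x),
    cols = c("beta_j", "beta_c"), names_to = "index", values_to = "value")
  long$index <- factor(long$index, levels = c("beta_j", "beta_c"),
                       labels = c("Jaccard similarity", "Cody turnover"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = if (is.null(matrix)) "Lower belt index"
                      else "Lower belt midpoint (m)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the NRI elevational profile
#'
#' NRI per belt midpoint with the zero line (clustering above, over-
#' dispersion below); non-evaluable belts are omitted.
#'
#' @param nri An [nri_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_nri_profile <- function(nri) {
  dat <- dplyr::filter(nri, .data$evaluable)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$midpoint, y = .data$nri)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Belt midpoint elevation (m)",
                  y = "Net relatedness index") +
    ggplot2::theme_minimal()
}

#' Autoplot a trend fit
#'
#' Observed points with the fitted curve (on the response scale for the
#' log-link quasi-Poisson fits).
#'
#' @param object A `trend_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  dat <- tibble::tibble(x = object$fit$model[[2]], y = object$fit$model[[1]])
  grid <- tibble::tibble(x = seq(min(dat$x), max(dat$x), length.out = 100))
  grid$y <- stats::predict(object$fit, newdata = data.frame(x = grid$x),
                           type = "response")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = object$predictor, y = object$response,
                  title = sprintf("%s ~ %s (%s): slope %.3g, R2 %.2f, p %.3g",
                                  object$response, object$predictor,
                                  object$family, object$slope,
                                  object$pseudo_r2, object$p_value)) +
    ggplot2::theme_minimal()
}
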