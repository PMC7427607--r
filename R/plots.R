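#' Plot an R_T curve
#'
#' Coefficient of variation against noise amplitude on a log-x axis, with the
#' Poisson reference line `R_T = 1`.
#'
#' @param object A [rt_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sisr_rt_curve <- function(object, ...) {
  df <- dplyr::filter(object, .data$defined)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sigma, y = .data$rt)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(sigma), y = expression(R[T]),
                  title = "Spike-train regularity vs noise amplitude") +
    ggplot2::theme_minimal()
}

#' Plot a multiplexing heatmap
#'
#' Layer-2 minimum R_T over the multiplexing parameter plane; masked cells
#' (oscillatory / hyper-excitable at zero noise) are shown hatched grey.
#'
#' @param object A [multiplex_heatmap()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sisr_heatmap <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tau_m, y = .data$kappa_m)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$rt_min)) +
    ggplot2::geom_point(data = dplyr::filter(object,
                                             .data$status != "excitable"),
                        shape = 4, colour = "grey30") +
    ggplot2::scale_fill_viridis_c(option = "inferno", direction = -1,
                                  na.value = "grey85") +
    ggplot2::labs(x = expression(tau[m]), y = expression(kappa[m]),
                  fill = expression(R[T]^{min}),
                  title = "Layer-2 minimum R_T under multiplexing") +
    ggplot2::theme_minimal()
}

#' Plot the interaction potential landscape
#'
#' `U(v; w)` for one or more coupling strengths, at a fixed slow value `w`.
#'
#' @param layer A [layer_spec()] (its `kappa` is overridden by `kappas`).
#' @param w Slow-variable value.
#' @param kappas Coupling strengths to draw.
#' @param vbar Neighbour substitution passed to [potential()].
#' @param v_range Range of v.
#' @return A ggplot.
#' @export
plot_landscape <- function(layer, w = 0, kappas = c(0, 0.25, 0.5, 1),
                           vbar = "self", v_range = c(-2.8, 2.8)) {
  v <- seq(v_range[1], v_range[2], length.out = 400)
  df <- purrr::map_dfr(kappas, function(k) {
    lay <- layer; lay$kappa <- k
    tibble::tibble(v = v, U = potential(lay, v, w, vbar), kappa = k)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$U,
                                   colour = factor(.data$kappa))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "v", y = "U(v)", colour = expression(kappa),
                  title = sprintf("Interaction potential at w = %g", w)) +
    ggplot2::theme_minimal()
}
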