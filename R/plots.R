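# ggplot2 visualizations for the main result types.

#' @export
autoplot.boundary_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$radius * cos(.data$phi),
                                       .data$radius * sin(.data$phi))) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Extracted spindle boundary")
}

#' @export
autoplot.tactoid_fit <- function(object, boundary = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(boundary)) {
    p <- p + ggplot2::geom_point(
      data = boundary,
      ggplot2::aes(.data$radius * cos(.data$phi), .data$radius * sin(.data$phi)),
      size = 0.4, alpha = 0.5)
  }
  if (!object$degenerate) {
    bc <- make_tactoid_boundary(object$tac, n_points = 720)
    p <- p + ggplot2::geom_path(data = bc,
                                ggplot2::aes(.data$x, .data$y, color = .data$sector))
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("Pole-indented tactoid fit (L0 = %.1f µm)", object$L0))
}

#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$ok),
                  ggplot2::aes(.data$x, .data$rho_rel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (µm)", y = expression(rho[x] / rho[ref]),
                  title = "Axial microtubule density profile")
}

#' @export
autoplot.void_shape <- function(object, ...) {
  prof <- attr(object, "profile")
  ggplot2::ggplot(prof, ggplot2::aes(.data$x, .data$d_void)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$d_fit), color = "red") +
    ggplot2::labs(x = "x (µm)", y = "void diameter (µm)",
                  title = sprintf("Average void profile (waist %.2f, beta %.1f µm)",
                                  object$waist, object$beta))
}

#' @export
autoplot.interaction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$d, .data$U)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "center-to-center distance d (µm)",
                  y = expression(U[int] / k),
                  title = "Void-void interaction potential")
}

#' @export
autoplot.gii_ensemble <- function(object, max_curves = 20, ...) {
  sub <- dplyr::filter(object$curves,
                       .data$replicate %in% unique(.data$replicate)[seq_len(max_curves)])
  ggplot2::ggplot(sub, ggplot2::aes(.data$s, .data$gii, group = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_line(data = object$mean_curve,
                       ggplot2::aes(.data$s, .data$gii), inherit.aes = FALSE,
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 8), ylim = c(0, 3)) +
    ggplot2::labs(x = "separation s (µm)", y = expression(g[II](s)),
                  title = "Pair correlation of plate configurations")
}

#' @export
autoplot.plate_config <- function(object, ...) {
  a <- attr(object, "a"); b <- attr(object, "b")
  R <- attr(object, "boundary_radius")
  tt <- seq(0, 2 * pi, length.out = 90)
  ell <- purrr::map_dfr(seq_len(nrow(object)), function(k) {
    cs <- cos(object$phi[k]); sn <- sin(object$phi[k])
    tibble(id = k,
           x = object$x[k] + a / 2 * cos(tt) * cs - b / 2 * sin(tt) * sn,
           y = object$y[k] + a / 2 * cos(tt) * sn + b / 2 * sin(tt) * cs)
  })
  circ <- tibble(x = R * cos(tt), y = R * sin(tt))
  ggplot2::ggplot(ell, ggplot2::aes(.data$x, .data$y, group = .data$id)) +
    ggplot2::geom_polygon(fill = "grey40") +
    ggplot2::geom_path(data = circ, ggplot2::aes(group = NULL)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (µm)", y = "z (µm)",
                  title = "Metaphase-plate configuration")
}
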