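#' Plot methods
#'
#' `autoplot()` methods returning ggplot objects: profiles as intensity vs
#' q (or angle), fits as data plus fitted curve and components, broadening
#' fits as the integral-width regression line.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name fibrilscatter-plots
NULL

#' @rdname fibrilscatter-plots
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname fibrilscatter-plots
#' @export
autoplot.azimuthal_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$angle, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "azimuthal angle (deg)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname fibrilscatter-plots
#' @export
autoplot.equatorial_fit <- function(object, ...) {
  comp <- object$components
  curves <- purrr::map_dfr(seq_len(nrow(comp)), function(i) {
    fun <- if (comp$shape[i] == "asymmetric200") asymmetric_200 else
      gaussian_peak
    tibble(hkl = comp$hkl[i], q = object$data$q,
           intensity = fun(object$data$q, comp$q0[i], comp$sigma[i],
                           comp$height[i]))
  })
  ggplot2::ggplot(object$data, ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$hkl), linetype = 2) +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "intensity (a.u.)",
                  colour = "reflection") +
    ggplot2::theme_minimal()
}

#' @rdname fibrilscatter-plots
#' @param points Optional `(q0, d, delta_q)` points to overlay (e.g. the
#'   excluded 1-10/110 widths).
#' @export
autoplot.broadening_fit <- function(object, points = NULL, ...) {
  xmax <- if (!is.null(points)) max(points$q0^2 * points$d) * 1.1 else 500
  line <- tibble(x = seq(0, xmax, length.out = 50)) |>
    dplyr::mutate(y = object$delta_q0 + object$slope * .data$x)
  p <- ggplot2::ggplot(line, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(q^2 * d ~ (nm^-1)),
                  y = expression(delta * q ~ (nm^-1))) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(points, x = .data$q0^2 * .data$d,
                           y = .data$delta_q))
  }
  p
}

#' @rdname fibrilscatter-plots
#' @export
autoplot.sans_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$q, .data$intensity)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = expression(q ~ (nm^-1)), y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname fibrilscatter-plots
#' @export
autoplot.hydration_series <- function(object, ...) {
  ggplot2::ggplot(spacing_trend(object),
                  ggplot2::aes(.data$fraction, .data$d)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = expression(D[2] * O ~ fraction),
                  y = "interfibril spacing d (nm)") +
    ggplot2::theme_minimal()
}
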