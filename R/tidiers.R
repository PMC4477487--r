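#' Tidy methods for fitted objects
#'
#' broom-style accessors: `tidy()` returns one row per fitted component or
#' term, `glance()` a one-row model summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name fibrilscatter-tidiers
NULL

#' @rdname fibrilscatter-tidiers
#' @export
tidy.equatorial_fit <- function(x, ...) {
  x$components |>
    dplyr::mutate(fwhm = sigma_to_fwhm(.data$sigma),
                  delta_q = integral_breadth(.data$sigma))
}

#' @rdname fibrilscatter-tidiers
#' @export
glance.equatorial_fit <- function(x, ...) {
  tibble(n_components = nrow(x$components),
         d_200 = x$components$d[x$components$hkl == "200"],
         residual_rms = x$residual_rms, converged = x$converged)
}

#' @rdname fibrilscatter-tidiers
#' @export
tidy.broadening_fit <- function(x, ...) {
  tibble(term = c("delta_q0", "slope", "g", "L"),
         estimate = c(x$delta_q0, x$slope, x$g, x$L),
         unit = c("nm^-1", "nm^-1 per nm^-1", "", "nm"))
}

#' @rdname fibrilscatter-tidiers
#' @export
glance.broadening_fit <- function(x, ...) {
  tibble(L = x$L, g = x$g, delta_q0 = x$delta_q0, slope = x$slope,
         n_points = x$n_points)
}

#' @rdname fibrilscatter-tidiers
#' @export
tidy.azimuthal_fit <- function(x, ...) {
  tibble(component = c("narrow", "wide"),
         centre = c(x$narrow$centre, x$wide$centre),
         fwhm = c(x$narrow$fwhm, x$wide$fwhm),
         area = c(x$narrow$area, x$wide$area))
}

#' @rdname fibrilscatter-tidiers
#' @export
glance.azimuthal_fit <- function(x, ...) {
  tibble(narrow_fraction = x$narrow_fraction, background = x$background,
         residual_rms = x$residual_rms, converged = x$converged)
}

#' @rdname fibrilscatter-tidiers
#' @export
tidy.sans_fit <- function(x, ...) {
  tibble(term = c("q_peak", "sigma", "amplitude", "d",
                  "bg_amplitude", "bg_exponent", "bg_constant"),
         estimate = c(x$q_peak, x$sigma, x$amplitude, x$d,
                      unname(x$background)))
}

#' @rdname fibrilscatter-tidiers
#' @export
glance.sans_fit <- function(x, ...) {
  tibble(detected = x$detected, q_peak = x$q_peak, d = x$d,
         amplitude = x$amplitude, residual_sd = x$residual_sd)
}

#' @rdname fibrilscatter-tidiers
#' @export
tidy.monoclinic_cell <- function(x, ...) {
  tibble(term = c("a", "b", "gamma"),
         estimate = c(x$a, x$b, x$gamma),
         unit = c("nm", "nm", "degrees"))
}
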