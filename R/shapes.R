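#' Peak shape functions
#'
#' `gaussian_peak()` is the symmetric profile
#' `F0(q) = height * exp(-(q - q0)^2 / (2 sigma^2))`. `asymmetric_200()` is
#' the low-q-augmented shape used for the 200 reflection: equal to `F0` for
#' `q >= q0` and `F0(q) * (1 + 0.1 (q - q0)^2)` for `q < q0`, with the
#' asymmetry constant fixed at 0.1 nm^2. The shape is continuous at `q0`,
#' peaks there (for sigma^2 < 5 nm^-2), and its low-q flank always lies on or
#' above the pure Gaussian.
#'
#' @param q Evaluation points, nm^-1.
#' @param q0 Peak-maximum position, nm^-1.
#' @param sigma Gaussian width, nm^-1, > 0.
#' @param height Peak height at `q0`.
#' @return Intensities at `q`.
#' @export
gaussian_peak <- function(q, q0, sigma, height) {
  if (sigma <= 0) abort("`sigma` must be > 0", class = "fs_invalid")
  height * exp(-(q - q0)^2 / (2 * sigma^2))
}

#' @rdname gaussian_peak
#' @export
asymmetric_200 <- function(q, q0, sigma, height) {
  f0 <- gaussian_peak(q, q0, sigma, height)
  ifelse(q < q0, f0 * (1 + asym_coeff_200 * (q - q0)^2), f0)
}

# low-q asymmetry coefficient of the 200 shape, nm^2 (fixed, not fitted)
asym_coeff_200 <- 0.1

#' FWHM / Gaussian-sigma conversion
#'
#' `fwhm = sigma * 2 sqrt(2 ln 2)`.
#'
#' @param sigma,fwhm Width parameters in matching units.
#' @return The converted width.
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Integral breadth of a fitted peak
#'
#' The integral breadth `delta q` is peak area divided by peak height,
#' defined on the symmetric part `F0` of the shape; for a Gaussian this is
#' `sigma * sqrt(2 pi)` in closed form. The low-q asymmetric augmentation of
#' the 200 shape is excluded by definition.
#'
#' @param x A Gaussian `sigma` (numeric, nm^-1) or an `equatorial_fit`.
#' @param ... Passed to methods.
#' @return For numeric input, the breadth(s) `sigma * sqrt(2 pi)` in nm^-1;
#'   for an `equatorial_fit`, a tibble with one row per fitted component.
#' @export
integral_breadth <- function(x, ...) UseMethod("integral_breadth")

#' @export
integral_breadth.numeric <- function(x, ...) {
  if (any(x <= 0)) abort("`sigma` must be > 0", class = "fs_invalid")
  x * sqrt(2 * pi)
}

#' @export
integral_breadth.equatorial_fit <- function(x, ...) {
  dplyr::mutate(x$components, delta_q = integral_breadth(.data$sigma)) |>
    dplyr::select("hkl", "q0", "d", "sigma", "delta_q")
}
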