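#' Radial scattering profile
#'
#' The common currency of all three scattering techniques: intensity sampled
#' against the scattering-vector magnitude `q`. Stored as a tibble with
#' columns `q` (nm^-1, strictly ascending), `intensity` (arbitrary counts;
#' may be negative after background subtraction) and optionally `sigma`
#' (per-point uncertainty, same units as `intensity`). Experiment metadata
#' travels in the `meta` attribute.
#'
#' @param q Scattering-vector magnitudes in nm^-1, strictly increasing,
#'   length >= 4.
#' @param intensity Intensities, same length as `q`.
#' @param sigma Optional per-point uncertainties, same length as `q`.
#' @param radiation Radiation label: `"x-ray-Cu"`, `"x-ray-Mo"` or
#'   `"neutron"` (or `NA`).
#' @param wavelength Wavelength in nm (> 0); required when `radiation` is set.
#' @param axis Axis label: `"equatorial"`, `"meridional"` or `"isotropic"`.
#' @param meta Additional metadata fields as a named list; merged over the
#'   explicit arguments.
#'
#' @return A `radial_profile` tibble.
#' @export
#' @examples
#' radial_profile(q = 1:10, intensity = rep(1, 10),
#'                radiation = "x-ray-Cu", wavelength = 0.15406)
radial_profile <- function(q, intensity, sigma = NULL,
                           radiation = NA_character_, wavelength = NA_real_,
                           axis = NA_character_, meta = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) < 4L) {
    abort("a radial profile needs at least 4 samples", class = "fs_invalid")
  }
  if (length(intensity) != length(q)) {
    abort("`q` and `intensity` must have the same length", class = "fs_invalid")
  }
  if (any(diff(q) <= 0)) {
    abort("`q` must be strictly increasing", class = "fs_invalid")
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      abort("`sigma` must match the length of `q`", class = "fs_invalid")
    }
  }
  if (!is.na(radiation)) {
    radiation <- match.arg(radiation, c("x-ray-Cu", "x-ray-Mo", "neutron"))
    if (is.na(wavelength) || wavelength <= 0) {
      abort("`wavelength` must be > 0 when `radiation` is set",
            class = "fs_invalid")
    }
  }
  df <- tibble(q = q, intensity = intensity)
  if (!is.null(sigma)) df$sigma <- sigma
  meta <- modifyList(
    list(radiation = radiation, wavelength_nm = wavelength, axis = axis),
    meta
  )
  new_radial_profile(df, meta)
}

new_radial_profile <- function(df, meta) {
  structure(df,
            meta = meta,
            class = c("radial_profile", class(tibble())))
}

#' Profile metadata
#'
#' @param x A `radial_profile` (or `pattern_grid`).
#' @return The metadata list.
#' @export
profile_meta <- function(x) attr(x, "meta", exact = TRUE) %||% list()

set_profile_meta <- function(x, ...) {
  attr(x, "meta") <- modifyList(profile_meta(x), list(...))
  x
}

#' @export
print.radial_profile <- function(x, ...) {
  m <- profile_meta(x)
  cat(sprintf("<radial_profile: %d points, q %.3g..%.3g nm^-1", nrow(x),
              min(x$q), max(x$q)))
  if (!is.null(m$radiation) && !is.na(m$radiation)) {
    cat(sprintf(", %s (lambda = %g nm)", m$radiation, m$wavelength_nm))
  }
  if (!is.null(m$axis) && !is.na(m$axis)) cat(", ", m$axis, sep = "")
  cat(">\n")
  NextMethod()
}

#' Azimuthal intensity profile
#'
#' Intensity against azimuthal angle around the fibre axis, used to describe
#' the orientation distribution of a reflection (e.g. the 200 arc).
#'
#' @param angle Angles in degrees, strictly increasing.
#' @param intensity Intensities, same length as `angle`.
#' @return An `azimuthal_profile` tibble.
#' @export
azimuthal_profile <- function(angle, intensity) {
  angle <- as.numeric(angle)
  intensity <- as.numeric(intensity)
  if (length(angle) != length(intensity)) {
    abort("`angle` and `intensity` must have the same length",
          class = "fs_invalid")
  }
  if (length(angle) < 4L) {
    abort("an azimuthal profile needs at least 4 samples", class = "fs_invalid")
  }
  if (any(diff(angle) <= 0)) {
    abort("`angle` must be strictly increasing", class = "fs_invalid")
  }
  structure(tibble(angle = angle, intensity = intensity),
            class = c("azimuthal_profile", class(tibble())))
}

#' Two-dimensional q x azimuth intensity grid
#'
#' A discretised fibre-diffraction pattern: intensity on a rectangular grid of
#' scattering-vector magnitude (rows) by azimuthal angle (columns).
#'
#' @param q Ascending q axis, nm^-1.
#' @param angle Ascending azimuthal axis, degrees.
#' @param intensity Matrix of dimension `length(q)` x `length(angle)`.
#' @param meta Optional metadata list (radiation, wavelength_nm, ...).
#' @return A `pattern_grid` object.
#' @export
pattern_grid <- function(q, angle, intensity, meta = list()) {
  q <- as.numeric(q); angle <- as.numeric(angle)
  if (any(diff(q) <= 0) || any(diff(angle) <= 0)) {
    abort("grid axes must be strictly increasing", class = "fs_invalid")
  }
  intensity <- as.matrix(intensity)
  if (!identical(dim(intensity), c(length(q), length(angle)))) {
    abort(sprintf("intensity matrix must be %d x %d to match the axes",
                  length(q), length(angle)), class = "fs_invalid")
  }
  structure(list(q = q, angle = angle, intensity = intensity, meta = meta),
            class = "pattern_grid")
}

#' @export
print.pattern_grid <- function(x, ...) {
  cat(sprintf("<pattern_grid: %d q x %d angle, q %.3g..%.3g nm^-1, angle %g..%g deg>\n",
              length(x$q), length(x$angle), min(x$q), max(x$q),
              min(x$angle), max(x$angle)))
  invisible(x)
}

#' Convert scattering angle to scattering-vector magnitude
#'
#' `q = 4 pi sin(theta) / lambda` where `two_theta = 2 theta` is the
#' scattering angle. `q_to_two_theta()` is the exact inverse.
#'
#' @param two_theta Scattering angle 2-theta in degrees, in `[0, 180)`.
#' @param wavelength Wavelength in nm, > 0.
#' @return Scattering-vector magnitude in nm^-1.
#' @export
#' @examples
#' two_theta_to_q(22.05, 0.15406)       # the 200 position for d = 0.403 nm
#' q_to_two_theta(15.59, 0.07071)       # same reflection with Mo radiation
two_theta_to_q <- function(two_theta, wavelength) {
  check_wavelength(wavelength)
  if (any(two_theta < 0 | two_theta >= 180)) {
    abort("`two_theta` must lie in [0, 180) degrees", class = "fs_invalid")
  }
  4 * pi * sin(two_theta * pi / 360) / wavelength
}

#' @param q Scattering-vector magnitude in nm^-1, with `q * lambda / (4 pi)`
#'   in `[0, 1)`.
#' @rdname two_theta_to_q
#' @export
q_to_two_theta <- function(q, wavelength) {
  check_wavelength(wavelength)
  s <- q * wavelength / (4 * pi)
  if (any(s < 0 | s >= 1)) {
    abort("`q` out of range for this wavelength", class = "fs_invalid")
  }
  2 * asin(s) * 180 / pi
}

check_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || length(wavelength) != 1L ||
      is.na(wavelength) || wavelength <= 0) {
    abort("`wavelength` must be a positive number (nm)", class = "fs_invalid")
  }
  invisible(wavelength)
}

#' Restrict a profile to a q window
#'
#' Keeps the samples with `qmin <= q <= qmax`; metadata is preserved.
#'
#' @param profile A `radial_profile`.
#' @param qmin,qmax Window bounds, nm^-1, `qmin < qmax`.
#' @return A `radial_profile` restricted to the window.
#' @export
crop_q <- function(profile, qmin, qmax) {
  stopifnot(inherits(profile, "radial_profile"))
  if (qmin >= qmax) abort("`qmin` must be < `qmax`", class = "fs_invalid")
  keep <- profile$q >= qmin & profile$q <= qmax
  if (!any(keep)) {
    abort("no samples fall inside the requested q window",
          class = "fs_empty_range")
  }
  out <- profile[keep, , drop = FALSE]
  new_radial_profile(as_tibble(out), profile_meta(profile))
}
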