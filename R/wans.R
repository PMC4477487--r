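#' Cuboid sample description for absorption correction
#'
#' @param thickness_along_beam Sample thickness along the incident beam, cm.
#' @param width,height Lateral dimensions, cm (the sample is assumed wider
#'   than the beam).
#' @param mu Linear attenuation coefficient, cm^-1.
#' @return A `cuboid_sample` object.
#' @export
cuboid_sample <- function(thickness_along_beam, width = 1.5, height = 1.5,
                          mu = 1) {
  vals <- c(thickness_along_beam, width, height, mu)
  if (any(!is.finite(vals)) || any(vals[1:3] <= 0) || mu < 0) {
    abort("sample dimensions must be positive and mu >= 0",
          class = "fs_invalid")
  }
  structure(list(thickness_along_beam = thickness_along_beam, width = width,
                 height = height, mu = mu),
            class = "cuboid_sample")
}

#' Transmission factor through a cuboid sample
#'
#' Averages the attenuation over the depth of the scattering event:
#' `(1/t) Int_0^t exp(-mu (x + (t - x)/cos(2 theta))) dx`, the incident path
#' to depth `x` plus the exit path through the downstream face at scattering
#' angle 2-theta in the equatorial plane. At `two_theta = 0` this reduces to
#' `exp(-mu t)` exactly. Numeric quadrature to better than 1e-6 relative.
#'
#' @param sample A [cuboid_sample()].
#' @param two_theta Scattering angle(s) in degrees, `0 <= two_theta < 90`.
#' @return Transmission factor(s) in `(0, 1]`.
#' @export
absorption_factor <- function(sample, two_theta) {
  stopifnot(inherits(sample, "cuboid_sample"))
  if (any(two_theta < 0 | two_theta >= 90)) {
    abort("`two_theta` must lie in [0, 90) degrees", class = "fs_invalid")
  }
  t <- sample$thickness_along_beam
  mu <- sample$mu
  if (mu == 0) return(rep(1, length(two_theta)))
  vapply(two_theta, function(tt) {
    cth <- cos(tt * pi / 180)
    # exit ray displaced laterally by (t - x) tan(2theta); worst case must
    # stay inside the downstream face
    if (t * tan(tt * pi / 180) > sample$width / 2) {
      abort(sprintf(paste("exit path at 2theta = %.1f deg leaves through a",
                          "side face not modelled by the cuboid geometry"),
                    tt),
            class = "fs_geometry")
    }
    integrate(function(x) exp(-mu * (x + (t - x) / cth)), 0, t,
              rel.tol = 1e-9)$value / t
  }, 0)
}

#' Correct a profile for sample absorption
#'
#' Divides the intensity pointwise by the [absorption_factor()] at each
#' point's scattering angle (computed from q via the wavelength carried in
#' the profile metadata). A metadata flag guards against double correction.
#'
#' @param profile A [radial_profile()] whose metadata includes
#'   `wavelength_nm`.
#' @param sample A [cuboid_sample()].
#' @return The corrected [radial_profile()].
#' @export
correct_absorption <- function(profile, sample) {
  stopifnot(inherits(profile, "radial_profile"))
  meta <- profile_meta(profile)
  if (isTRUE(meta$absorption_corrected)) {
    abort("profile is already absorption-corrected", class = "fs_config")
  }
  wl <- meta$wavelength_nm
  if (is.null(wl) || is.na(wl)) {
    abort("profile metadata lacks the wavelength needed to map q to angle",
          class = "fs_config")
  }
  tt <- q_to_two_theta(profile$q, wl)
  fac <- absorption_factor(sample, tt)
  out <- profile
  out$intensity <- profile$intensity / fac
  if ("sigma" %in% names(out)) out$sigma <- out$sigma / fac
  set_profile_meta(out, absorption_corrected = TRUE)
}

#' D minus H difference profile
#'
#' Subtracts a (scaled) H-form profile from the D-form profile on their
#' common q grid. Scaling of H equalises either nothing (`"none"`), the
#' total integrated intensity (`"total-intensity"`), or the integral over a
#' peak-free window (`"window"`, default 20-22 nm^-1). The H profile is
#' linearly resampled onto the D grid when the grids differ (flagged).
#'
#' @param d_profile,h_profile [radial_profile()]s covering a common q range.
#' @param normalisation `"none"`, `"total-intensity"` or `"window"`.
#' @param window Normalisation window `c(qmin, qmax)` for
#'   `normalisation = "window"`.
#' @return A `difference_profile` tibble (`q`, `delta_intensity`) with the
#'   applied `normalisation` scalar in its attributes.
#' @export
difference_profile <- function(d_profile, h_profile,
                               normalisation = c("window", "none",
                                                 "total-intensity"),
                               window = c(20, 22)) {
  stopifnot(inherits(d_profile, "radial_profile"),
            inherits(h_profile, "radial_profile"))
  normalisation <- match.arg(normalisation)
  qlo <- max(min(d_profile$q), min(h_profile$q))
  qhi <- min(max(d_profile$q), max(h_profile$q))
  if (qlo >= qhi) {
    abort("profiles have no common q range", class = "fs_invalid")
  }
  qd <- d_profile$q[d_profile$q >= qlo & d_profile$q <= qhi]
  yd <- d_profile$intensity[d_profile$q >= qlo & d_profile$q <= qhi]
  resampled <- !isTRUE(all.equal(qd, h_profile$q[h_profile$q >= qlo &
                                                   h_profile$q <= qhi]))
  yh <- if (resampled) {
    approx(h_profile$q, h_profile$intensity, xout = qd, rule = 2)$y
  } else {
    h_profile$intensity[h_profile$q >= qlo & h_profile$q <= qhi]
  }
  s <- switch(normalisation,
    "none" = 1,
    "total-intensity" = sum(yd) / sum(yh),
    "window" = {
      sel <- qd >= window[1] & qd <= window[2]
      if (sum(sel) < 3L) {
        abort("normalisation window contains fewer than 3 points",
              class = "fs_config")
      }
      sum(yd[sel]) / sum(yh[sel])
    })
  structure(tibble(q = qd, delta_intensity = yd - s * yh),
            normalisation = s, resampled = resampled,
            class = c("difference_profile", class(tibble())))
}

#' Jointly fit H- and D-form equatorial patterns with a shared lattice
#'
#' Fits both patterns simultaneously under the hypothesis that deuteration
#' leaves all reflection positions and widths unchanged and alters only the
#' per-reflection intensities. The two patterns carry different 1-10/110
#' height ratios, which breaks the width/splitting degeneracy of the
#' overlapped doublet far more effectively than fitting either pattern
#' alone; the monoclinic angle implied by the shared spacings is returned
#' with the fit.
#'
#' @param h_profile,d_profile Equatorial [radial_profile()]s of the H and D
#'   forms on a common q grid.
#' @param overlap_width_ratio Width tie for the 1-10/110 pair relative to
#'   the 200 (see [fit_equatorial()]).
#' @param include_100 Model the weak 100 shoulder (default TRUE).
#' @return An `equatorial_pair_fit`: `components` tibble (`hkl`, `q0`, `d`,
#'   `sigma`, `height_h`, `height_d`, `deuteration_scale`), per-pattern
#'   background parameters, the implied [monoclinic_cell()], residual RMS
#'   and convergence flag.
#' @export
fit_equatorial_pair <- function(h_profile, d_profile,
                                overlap_width_ratio = 1.5,
                                include_100 = TRUE) {
  stopifnot(inherits(h_profile, "radial_profile"),
            inherits(d_profile, "radial_profile"))
  if (!isTRUE(all.equal(h_profile$q, d_profile$q))) {
    abort("H and D profiles must share one q grid", class = "fs_invalid")
  }
  q <- h_profile$q; yh <- h_profile$intensity; yd <- d_profile$intensity
  n_pk <- if (include_100) 5L else 4L
  single <- function(p, hh, bg) {
    sov <- overlap_width_ratio * p[["s200"]]
    # h00 harmonics pinned to the 200: q400 = 2 q200, q100 = q200 / 2
    out <- bg[1] * q^(-bg[2]) + bg[3] +
      gaussian_peak(q, p[["q1m10"]], sov, hh[1]) +
      gaussian_peak(q, p[["q1m10"]] + p[["dq110"]], sov, hh[2]) +
      asymmetric_200(q, p[["q200"]], p[["s200"]], hh[3]) +
      gaussian_peak(q, 2 * p[["q200"]], p[["s400"]], hh[4])
    if (include_100) {
      out <- out + gaussian_peak(q, p[["q200"]] / 2, p[["s100"]], hh[5])
    }
    out
  }
  heights <- function(p, suffix) {
    vapply(paste0("h", seq_len(n_pk), suffix), function(nm) p[[nm]], 0)
  }
  res <- function(p) {
    c(single(p, heights(p, "h"), c(p[["Ah"]], p[["eh"]], p[["ch"]])) - yh,
      single(p, heights(p, "d"), c(p[["Ad"]], p[["ed"]], p[["cd"]])) - yd)
  }
  ymax <- max(yh)
  p0 <- c(q1m10 = 10.6, dq110 = 0.45, q200 = 15.6, s200 = 0.73,
          s400 = 1, s100 = 0.73,
          setNames(ymax * c(0.4, 0.5, 1, 0.05, 0.04)[seq_len(n_pk)],
                   paste0("h", seq_len(n_pk), "h")),
          setNames(ymax * c(0.2, 0.45, 1.1, 0.05, 0.04)[seq_len(n_pk)],
                   paste0("h", seq_len(n_pk), "d")),
          Ah = 5, eh = 1.5, ch = min(yh), Ad = 5, ed = 1.5, cd = min(yd))
  lo <- c(q1m10 = 9.3, dq110 = 0.05, q200 = 14.6, s200 = 0.2,
          s400 = 0.2, s100 = 0.2,
          setNames(rep(0, 2 * n_pk),
                   c(paste0("h", seq_len(n_pk), "h"),
                     paste0("h", seq_len(n_pk), "d"))),
          Ah = 0, eh = 0.1, ch = -Inf, Ad = 0, ed = 0.1, cd = -Inf)
  hi <- c(q1m10 = 11.6, dq110 = 1.5, q200 = 16.6, s200 = 2,
          s400 = 2.5, s100 = 2,
          setNames(rep(Inf, 2 * n_pk),
                   c(paste0("h", seq_len(n_pk), "h"),
                     paste0("h", seq_len(n_pk), "d"))),
          Ah = Inf, eh = 6, ch = Inf, Ad = Inf, ed = 6, cd = Inf)
  if (!include_100) {
    keep <- setdiff(names(p0), "s100")
    p0 <- p0[keep]; lo <- lo[keep]; hi <- hi[keep]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = res, lower = lo, upper = hi,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, maxfev = 20000)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    abort("joint H/D equatorial fit did not converge",
          class = "fs_fit_failure")
  }
  p <- fit$par
  sov <- overlap_width_ratio * p[["s200"]]
  hkl <- c("1-10", "110", "200", "400", if (include_100) "100")
  q0 <- c(p[["q1m10"]], p[["q1m10"]] + p[["dq110"]], p[["q200"]],
          2 * p[["q200"]], if (include_100) p[["q200"]] / 2)
  sig <- c(sov, sov, p[["s200"]], p[["s400"]], if (include_100) p[["s100"]])
  comp <- tibble(hkl = hkl, q0 = q0, d = 2 * pi / q0, sigma = sig,
                 height_h = unname(heights(p, "h")),
                 height_d = unname(heights(p, "d"))) |>
    dplyr::mutate(deuteration_scale = .data$height_d / .data$height_h)
  cell <- invert_cell(comp$d[1], comp$d[2], comp$d[3])
  structure(list(components = comp,
                 background_h = c(amplitude = p[["Ah"]],
                                  exponent = p[["eh"]], constant = p[["ch"]]),
                 background_d = c(amplitude = p[["Ad"]],
                                  exponent = p[["ed"]], constant = p[["cd"]]),
                 cell = cell,
                 residual_rms = sqrt(fit$deviance / (2 * length(q))),
                 converged = TRUE),
            class = "equatorial_pair_fit")
}

#' @export
print.equatorial_pair_fit <- function(x, ...) {
  cat(sprintf("<equatorial_pair_fit: shared lattice gamma = %.2f deg, residual RMS %.4g>\n",
              x$cell$gamma, x$residual_rms))
  print(x$components)
  invisible(x)
}

#' Localise a reflection from a difference-profile lobe
#'
#' Fits a single Gaussian plus constant to a window of a D-H difference
#' profile. Fitting the negative 1-10 lobe of the equatorial difference
#' pins the 1-10 position even when the 1-10/110 doublet is unresolvable in
#' the individual patterns — deuteration suppresses the 1-10 far more than
#' the 110, so the difference isolates it.
#'
#' @param diff A `difference_profile`.
#' @param window `c(qmin, qmax)` window containing the lobe.
#' @param sign `-1` (default) to fit a negative lobe, `+1` for positive.
#' @return List with `q0`, `sigma`, `depth` (signed height) and `converged`.
#' @export
locate_difference_lobe <- function(diff, window = c(9, 13), sign = -1) {
  stopifnot(inherits(diff, "difference_profile"))
  sel <- diff$q >= window[1] & diff$q <= window[2]
  if (sum(sel) < 10L) {
    abort("lobe window contains fewer than 10 points", class = "fs_invalid")
  }
  x <- diff$q[sel]
  yv <- sign * diff$delta_intensity[sel]   # flip so the lobe is a maximum
  q0_0 <- x[which.max(yv)]
  h0 <- max(yv) - median(yv)
  p0 <- c(q0 = q0_0, sigma = 1, h = max(h0, 1e-9), c = min(yv))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) {
      p[["h"]] * exp(-(x - p[["q0"]])^2 / (2 * p[["sigma"]]^2)) +
        p[["c"]] - yv
    }, lower = c(window[1], 0.1, 0, -Inf),
       upper = c(window[2], diff(window), Inf, Inf),
       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    abort("difference-lobe fit failed", class = "fs_fit_failure")
  }
  p <- fit$par
  list(q0 = p[["q0"]], sigma = p[["sigma"]], depth = sign * p[["h"]],
       converged = fit$info %in% 1:4)
}

#' Compare H- and D-form equatorial d-spacings
#'
#' Per-reflection relative d-spacing differences between two equatorial
#' fits; the comparison passes when every shared reflection agrees within
#' the tolerance, supporting the inference that deuterated (accessible) and
#' inaccessible domains share one lattice.
#'
#' @param h_fit,d_fit `equatorial_fit`s of the H and D forms (both must
#'   contain the 200 reflection).
#' @param tolerance Maximum relative |d(D) - d(H)| / d(H) (default 0.005).
#' @param reflections Reflections to compare; default all shared ones. A
#'   fitted weak shoulder (100) can be excluded here when its position is
#'   too poorly determined for the comparison to be meaningful.
#' @return A tibble (`hkl`, `d_h`, `d_d`, `rel_diff`, `within`) with a
#'   `pass` attribute.
#' @export
check_equatorial_consistency <- function(h_fit, d_fit, tolerance = 0.005,
                                         reflections = NULL) {
  stopifnot(inherits(h_fit, "equatorial_fit"),
            inherits(d_fit, "equatorial_fit"))
  if (!"200" %in% h_fit$components$hkl || !"200" %in% d_fit$components$hkl) {
    abort("both fits must contain the 200 reflection", class = "fs_invalid")
  }
  tab <- dplyr::inner_join(
    dplyr::select(h_fit$components, "hkl", d_h = "d"),
    dplyr::select(d_fit$components, "hkl", d_d = "d"),
    by = "hkl")
  if (!is.null(reflections)) {
    tab <- dplyr::filter(tab, .data$hkl %in% reflections)
  }
  tab <- tab |>
    dplyr::mutate(rel_diff = abs(.data$d_d - .data$d_h) / .data$d_h,
                  within = .data$rel_diff <= tolerance)
  structure(tab, pass = all(tab$within), tolerance = tolerance)
}

#' Detect meridional 00l reflections in a difference profile
#'
#' Searches windows centred at `q = 2 pi l / c` (l = 1..4) of the meridional
#' D-H difference for peaks exceeding `threshold_sigma` times the noise
#' level (estimated robustly from the off-window samples). In deuterated
#' cellulose these reflections mark longitudinal-stagger irregularity of the
#' accessible surface chains.
#'
#' @param meridional_difference A `difference_profile` of meridional D and H
#'   profiles.
#' @param fibre_repeat_c Fibre repeat c in nm (default 1.038).
#' @param threshold_sigma Detection threshold in noise-sd units (default 3).
#' @param orders Reflection orders l to search (default 1:4).
#' @param half_width Window half-width around each 00l position, nm^-1.
#' @return Tibble (`l`, `q_expected`, `q_found`, `amplitude`,
#'   `significance`, `detected`), one row per order whose window is covered.
#' @export
detect_meridional <- function(meridional_difference, fibre_repeat_c = 1.038,
                              threshold_sigma = 3, orders = 1:4,
                              half_width = 1) {
  stopifnot(inherits(meridional_difference, "difference_profile"))
  q <- meridional_difference$q
  y <- meridional_difference$delta_intensity
  q00l <- 2 * pi * orders / fibre_repeat_c
  covered <- q00l - half_width >= min(q) & q00l + half_width <= max(q)
  if (!all(covered)) {
    warn(sprintf("orders %s fall outside the profile q range",
                 paste(orders[!covered], collapse = ", ")))
  }
  in_any_window <- rep(FALSE, length(q))
  for (qq in q00l[covered]) {
    in_any_window <- in_any_window | abs(q - qq) <= half_width
  }
  purrr::map_dfr(which(covered), function(i) {
    # noise and baseline taken from the window's own flanks: the relative
    # noise model makes the noise level q-dependent
    flank <- !in_any_window & abs(q - q00l[i]) <= 2 * half_width
    if (sum(flank) < 5L) flank <- !in_any_window
    noise_sd <- mad(y[flank])
    if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- sd(y[flank])
    base <- median(y[flank])
    # integrated excess over a core centred on the expected position; the
    # summed statistic is ~N(0, noise_sd * sqrt(n)) under pure noise, giving
    # calibrated false-positive control at threshold_sigma
    core <- abs(q - q00l[i]) <= half_width / 2
    n_core <- sum(core)
    excess_sum <- sum(y[core] - base)
    significance <- excess_sum / (noise_sd * sqrt(n_core))
    sel <- abs(q - q00l[i]) <= half_width
    amp <- max(y[sel]) - base
    tibble(l = orders[i], q_expected = q00l[i],
           q_found = q[sel][which.max(y[sel])],
           amplitude = amp, significance = significance,
           detected = significance > threshold_sigma)
  })
}
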