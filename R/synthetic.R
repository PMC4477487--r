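#' Ground truth for synthetic scattering patterns
#'
#' The full generative parameter set for the synthetic WAXS/WANS/SANS
#' profiles. The defaults describe a bamboo-like specimen: a gamma = 92 deg
#' hk0 cell with intersheet spacing d200 = 0.403 nm, Scherrer column length
#' L = 3.84 nm perpendicular to \[200\], disorder parameter g = 0.036, a
#' narrow-plus-wide orientation distribution, interfibril SANS spacings
#' 2.96 nm (dry) to 3.19 nm (25% D2O), and 1% relative Gaussian noise.
#'
#' @param cell A [monoclinic_cell()]; default has gamma = 92 deg and
#'   d200 = 0.403 nm.
#' @param fibre_repeat_c Fibre repeat c in nm (meridional 00l positions).
#' @param column_length_200 True Scherrer dimension L perpendicular to
#'   \[200\], nm, > 0.
#' @param disorder_g Paracrystalline disorder parameter, in `[0, 0.2)`.
#' @param peak_heights Named relative heights for the equatorial
#'   reflections `1-10`, `110`, `200`, `400` and optional `100`.
#' @param overlap_breadth_factor Width of the 1-10/110 (and 100) reflections
#'   relative to the 200 width; in overlapped doublets this broadening is
#'   only qualitatively constrained, so the factor is a free parameter.
#' @param orientation List with `narrow_fwhm`, `wide_fwhm` (degrees,
#'   narrow < wide), `narrow_fraction` in (0, 1), `centre` (degrees),
#'   `total_area` and `background` for the azimuthal distribution.
#' @param sans_spacing Named numeric: interfibril spacing (nm) at the named
#'   D2O volume fractions; linearly interpolated between, clamped outside.
#' @param sans_breadth Gaussian sigma of the SANS Bragg peak, nm^-1.
#' @param sans_peak_height Peak height at full D2O contrast.
#' @param sans_background Named numeric `(amplitude, exponent, constant)`
#'   power-law background for SANS.
#' @param deuteration_scale Named multiplicative intensity factors applied to
#'   the equatorial reflections in the D form.
#' @param meridional_heights Heights of the 00l reflections (l = 1, 2, ...)
#'   present in the D form only.
#' @param meridional_sigma Gaussian sigma of the 00l reflections, nm^-1.
#' @param background Named numeric `(amplitude, exponent, constant)`:
#'   wide-angle background `amplitude * q^-exponent + constant`.
#' @param noise_fraction Relative Gaussian noise level (sd as a fraction of
#'   local intensity), >= 0.
#' @param noise_model `"relative"` (Gaussian, sd proportional to intensity)
#'   or `"poisson"` (counts drawn per point with mean
#'   `intensity / noise_fraction^2`, rescaled).
#' @param seed Integer RNG seed used by all generators.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(cell = monoclinic_cell(2 * 0.403 / sin(92 * pi / 180),
                                                0.820, 92),
                         fibre_repeat_c = 1.038,
                         column_length_200 = 3.84,
                         disorder_g = 0.036,
                         peak_heights = c("1-10" = 0.45, "110" = 0.55,
                                          "200" = 1, "400" = 0.05,
                                          "100" = 0.04),
                         overlap_breadth_factor = 1.5,
                         orientation = list(narrow_fwhm = 15, wide_fwhm = 60,
                                            narrow_fraction = 0.6, centre = 0,
                                            total_area = 100, background = 0.5),
                         sans_spacing = c("0" = 2.96, "0.25" = 3.19),
                         sans_breadth = 0.25,
                         sans_peak_height = 1,
                         sans_background = c(amplitude = 0.05, exponent = 3,
                                             constant = 0.02),
                         deuteration_scale = c("1-10" = 0.5, "110" = 0.9,
                                               "200" = 1.1, "400" = 1,
                                               "100" = 1),
                         meridional_heights = c(0.3, 0.15),
                         meridional_sigma = 0.25,
                         background = c(amplitude = 5, exponent = 1.5,
                                        constant = 0.2),
                         noise_fraction = 0.01,
                         noise_model = c("relative", "poisson"),
                         seed = 1L) {
  stopifnot(inherits(cell, "monoclinic_cell"))
  noise_model <- match.arg(noise_model)
  if (column_length_200 <= 0) {
    abort("`column_length_200` must be > 0", class = "fs_config")
  }
  if (disorder_g < 0 || disorder_g >= 0.2) {
    abort("`disorder_g` must lie in [0, 0.2)", class = "fs_config")
  }
  nf <- orientation$narrow_fraction
  if (is.null(nf) || nf <= 0 || nf >= 1) {
    abort("`orientation$narrow_fraction` must lie in (0, 1)",
          class = "fs_config")
  }
  if (noise_fraction < 0) {
    abort("`noise_fraction` must be >= 0", class = "fs_config")
  }
  structure(list(cell = cell, fibre_repeat_c = fibre_repeat_c,
                 column_length_200 = column_length_200,
                 disorder_g = disorder_g, peak_heights = peak_heights,
                 overlap_breadth_factor = overlap_breadth_factor,
                 orientation = orientation, sans_spacing = sans_spacing,
                 sans_breadth = sans_breadth,
                 sans_peak_height = sans_peak_height,
                 sans_background = sans_background,
                 deuteration_scale = deuteration_scale,
                 meridional_heights = meridional_heights,
                 meridional_sigma = meridional_sigma,
                 background = background, noise_fraction = noise_fraction,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "ground_truth")
}

#' True equatorial peak table for a ground truth
#'
#' Positions from the hk0 cell; 200/400 widths from the broadening law
#' `delta q = 2 pi / L + (pi/2) g^2 q0^2 d200`; 1-10/110/100 widths equal to
#' the 200 width times `overlap_breadth_factor` (100 uses factor 1).
#'
#' @param truth A [ground_truth()].
#' @return Tibble with columns `hkl`, `q0`, `d`, `sigma`, `height`, `shape`.
#' @export
truth_peak_table <- function(truth) {
  refl <- names(truth$peak_heights)
  tab <- cell_reflections(truth$cell, refl)
  d200 <- d_spacing(truth$cell, 2, 0)
  delta_q0 <- 2 * pi / truth$column_length_200
  law <- function(q0) delta_q0 + (pi / 2) * truth$disorder_g^2 * q0^2 * d200
  sigma200 <- law(tab$q0[tab$hkl == "200"]) / sqrt(2 * pi)
  tab |>
    dplyr::mutate(
      sigma = dplyr::case_when(
        .data$hkl %in% c("200", "400") ~ law(.data$q0) / sqrt(2 * pi),
        .data$hkl %in% c("1-10", "110") ~ sigma200 * truth$overlap_breadth_factor,
        TRUE ~ sigma200),
      height = unname(truth$peak_heights[.data$hkl]),
      shape = dplyr::if_else(.data$hkl == "200", "asymmetric200", "gaussian"))
}

power_background <- function(q, pars) {
  pars[["amplitude"]] * q^(-pars[["exponent"]]) + pars[["constant"]]
}

equatorial_model <- function(q, peaks, background = NULL) {
  y <- if (is.null(background)) rep(0, length(q)) else
    power_background(q, background)
  for (i in seq_len(nrow(peaks))) {
    fun <- if (peaks$shape[i] == "asymmetric200") asymmetric_200 else
      gaussian_peak
    if (peaks$height[i] > 0) {
      y <- y + fun(q, peaks$q0[i], peaks$sigma[i], peaks$height[i])
    }
  }
  y
}

add_noise <- function(intensity, truth, seed) {
  nf <- truth$noise_fraction
  if (nf <= 0) return(intensity)
  withr::with_seed(seed, {
    if (truth$noise_model == "poisson") {
      # expected counts intensity / nf^2 so that relative sd ~ nf at unit
      # intensity; rescaled back to the input units
      lam <- pmax(intensity, 0) / nf^2
      stats::rpois(length(lam), lam) * nf^2
    } else {
      intensity * (1 + rnorm(length(intensity), sd = nf))
    }
  })
}

#' Generate a synthetic equatorial WAXS profile
#'
#' Power-law background plus the equatorial reflections of the ground-truth
#' cell, with the 200 reflection taking the asymmetric shape and the 200/400
#' integral widths following the size/disorder broadening law. Noise is
#' seeded: the same truth and seed give bit-identical output.
#'
#' @param truth A [ground_truth()].
#' @param q_grid Ascending q grid in nm^-1, spanning at least `[5, 35]` by
#'   default and wide enough to contain the 400 reflection.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @param wavelength,radiation Metadata recorded on the profile.
#' @return A [radial_profile()] (equatorial axis).
#' @export
generate_equatorial_waxs <- function(truth, q_grid = seq(5, 35, by = 0.02),
                                     seed = truth$seed,
                                     wavelength = 0.15406,
                                     radiation = "x-ray-Cu") {
  stopifnot(inherits(truth, "ground_truth"))
  peaks <- truth_peak_table(truth)
  q400 <- peaks$q0[peaks$hkl == "400"]
  if (length(q400) && max(q_grid) < q400) {
    abort("`q_grid` too narrow: does not contain the 400 reflection",
          class = "fs_config")
  }
  y <- equatorial_model(q_grid, peaks, truth$background)
  radial_profile(q = q_grid, intensity = add_noise(y, truth, seed),
                 radiation = radiation, wavelength = wavelength,
                 axis = "equatorial")
}

orientation_shape <- function(angle, orientation) {
  sn <- fwhm_to_sigma(orientation$narrow_fwhm)
  sw <- fwhm_to_sigma(orientation$wide_fwhm)
  fn <- orientation$narrow_fraction
  ctr <- orientation$centre
  narrow <- exp(-(angle - ctr)^2 / (2 * sn^2)) / (sn * sqrt(2 * pi))
  wide <- exp(-(angle - ctr)^2 / (2 * sw^2)) / (sw * sqrt(2 * pi))
  list(narrow = fn * narrow, wide = (1 - fn) * wide)
}

#' Generate a synthetic azimuthal profile
#'
#' Sum of a narrow and a wide Gaussian sharing a centre (unit-area shapes
#' scaled by `total_area` and split by `narrow_fraction`), plus a constant
#' background and seeded noise.
#'
#' @inheritParams generate_equatorial_waxs
#' @param angle_grid Ascending angles in degrees covering at least 180 deg.
#' @return An [azimuthal_profile()].
#' @export
generate_azimuthal <- function(truth, angle_grid = seq(-90, 90, by = 1),
                               seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  ori <- truth$orientation
  if (ori$narrow_fwhm >= ori$wide_fwhm) {
    abort("narrow_fwhm must be < wide_fwhm", class = "fs_config")
  }
  if (diff(range(angle_grid)) < 180) {
    abort("`angle_grid` must cover at least 180 degrees", class = "fs_config")
  }
  sh <- orientation_shape(angle_grid, ori)
  y <- ori$total_area * (sh$narrow + sh$wide) + ori$background
  azimuthal_profile(angle_grid, add_noise(y, truth, seed))
}

#' Generate a synthetic 2D q x azimuth grid
#'
#' Outer-product construction: at each q the oriented (crystalline) equatorial
#' intensity is spread over azimuth as the narrow + wide orientation mixture,
#' and the isotropic background is spread uniformly. Integrating over azimuth
#' recovers the equatorial profile up to noise.
#'
#' @inheritParams generate_azimuthal
#' @param q_grid Ascending q grid, nm^-1.
#' @return A [pattern_grid()].
#' @export
generate_pattern_grid <- function(truth, q_grid = seq(5, 35, by = 0.1),
                                  angle_grid = seq(-90, 90, by = 3),
                                  seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  ori <- truth$orientation
  if (ori$narrow_fwhm >= ori$wide_fwhm) {
    abort("narrow_fwhm must be < wide_fwhm", class = "fs_config")
  }
  peaks <- truth_peak_table(truth)
  oriented <- equatorial_model(q_grid, peaks, background = NULL)
  bg <- power_background(q_grid, truth$background)
  sh <- orientation_shape(angle_grid, ori)
  span <- diff(range(angle_grid))
  m <- outer(oriented, sh$narrow + sh$wide) + outer(bg, rep(1 / span,
                                                            length(angle_grid)))
  noisy <- add_noise(as.vector(m), truth, seed)
  pattern_grid(q_grid, angle_grid,
               matrix(noisy, nrow = length(q_grid)),
               meta = list(radiation = "x-ray-Cu", wavelength_nm = 0.15406))
}

interp_sans_spacing <- function(truth, d2o_fraction) {
  fr <- as.numeric(names(truth$sans_spacing))
  sp <- unname(truth$sans_spacing)
  if (length(fr) == 1L) return(sp)
  approx(fr, sp, xout = d2o_fraction, rule = 2)$y
}

#' Generate a synthetic SANS profile
#'
#' Power-law + constant background plus one Gaussian interfibril Bragg peak
#' at `q = 2 pi / spacing(d2o_fraction)`. The peak amplitude is scaled by the
#' squared contrast between cellulose and the D2O/H2O mixture (relative to
#' pure D2O), so it vanishes exactly at the contrast-match fraction.
#'
#' @inheritParams generate_equatorial_waxs
#' @param d2o_fraction D2O volume fraction in `[0, 1]`.
#' @param q_grid Ascending q grid, nm^-1 (default 0.4-2.8).
#' @return A [radial_profile()] (neutron).
#' @export
generate_sans <- function(truth, d2o_fraction,
                          q_grid = seq(0.4, 2.8, by = 0.01),
                          seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (d2o_fraction < 0 || d2o_fraction > 1) {
    abort("`d2o_fraction` must lie in [0, 1]", class = "fs_invalid")
  }
  spacing <- interp_sans_spacing(truth, d2o_fraction)
  scale <- contrast_factor(d2o_fraction) / contrast_factor(1)
  y <- power_background(q_grid, truth$sans_background) +
    gaussian_peak(q_grid, 2 * pi / spacing, truth$sans_breadth,
                  truth$sans_peak_height * scale)
  radial_profile(q_grid, add_noise(y, truth, seed),
                 radiation = "neutron", wavelength = 0.35,
                 axis = "equatorial",
                 meta = list(d2o_fraction = d2o_fraction))
}

#' Generate a paired H/D WANS data set
#'
#' Four profiles: equatorial H and D forms sharing one lattice, with the D
#' heights multiplied per-reflection by `deuteration_scale` (positions
#' unchanged), and meridional H and D forms in which the 00l reflections at
#' `q = 2 pi l / c` appear only after deuteration.
#'
#' @inheritParams generate_equatorial_waxs
#' @param q_grid Equatorial q grid, nm^-1.
#' @param q_grid_meridional Meridional q grid, nm^-1.
#' @return A named list of four [radial_profile()]s: `h`, `d`,
#'   `h_meridional`, `d_meridional`.
#' @export
generate_wans_pair <- function(truth, q_grid = seq(5, 35, by = 0.02),
                               q_grid_meridional = seq(2, 16, by = 0.02),
                               seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  need <- c("1-10", "200")
  if (!all(need %in% names(truth$deuteration_scale))) {
    abort("`deuteration_scale` must cover at least the 1-10 and 200 reflections",
          class = "fs_config")
  }
  peaks <- truth_peak_table(truth)
  scl <- truth$deuteration_scale[peaks$hkl]
  scl[is.na(scl)] <- 1
  peaks_d <- dplyr::mutate(peaks, height = .data$height * unname(scl))
  mk_eq <- function(pk, s) {
    y <- equatorial_model(q_grid, pk, truth$background)
    radial_profile(q_grid, add_noise(y, truth, s), radiation = "neutron",
                   wavelength = 0.242, axis = "equatorial")
  }
  l <- seq_along(truth$meridional_heights)
  q00l <- 2 * pi * l / truth$fibre_repeat_c
  mk_mer <- function(with_peaks, s) {
    y <- power_background(q_grid_meridional, truth$background)
    if (with_peaks) {
      for (i in l) {
        y <- y + gaussian_peak(q_grid_meridional, q00l[i],
                               truth$meridional_sigma,
                               truth$meridional_heights[i])
      }
    }
    radial_profile(q_grid_meridional, add_noise(y, truth, s),
                   radiation = "neutron", wavelength = 0.242,
                   axis = "meridional")
  }
  list(h = mk_eq(peaks, seed),
       d = mk_eq(peaks_d, seed + 1L),
       h_meridional = mk_mer(FALSE, seed + 2L),
       d_meridional = mk_mer(TRUE, seed + 3L))
}
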