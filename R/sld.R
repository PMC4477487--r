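#' Neutron scattering-length density
#'
#' An `sld_spec` describes a material by its formula-unit composition
#' (isotope-aware element counts; `"D"` is deuterium) and mass density.
#' [sld()] converts it to a coherent scattering-length density:
#' `SLD = (sum of counts * b_coh) * rho * N_A / M`, reported in nm^-2
#' (1 nm^-2 = 1e2 Angstrom^-2 ... i.e. 6.36e-4 nm^-2 is the familiar
#' 6.36e-6 Angstrom^-2 of D2O).
#'
#' @param composition Named numeric vector of element counts per formula
#'   unit, e.g. `c(C = 6, H = 10, O = 5)`; names among H, D, C, N, O.
#' @param mass_density Mass density in g cm^-3, > 0.
#' @return An `sld_spec` object.
#' @export
#' @examples
#' sld(sld_spec(c(D = 2, O = 1), 1.105))   # D2O: ~6.36e-4 nm^-2
sld_spec <- function(composition, mass_density) {
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    abort("`composition` must be a named vector of element counts",
          class = "fs_invalid")
  }
  unknown <- setdiff(names(composition), names(coherent_b_fm))
  if (length(unknown)) {
    abort(sprintf("no coherent scattering length tabulated for: %s",
                  paste(unknown, collapse = ", ")),
          class = "fs_lookup")
  }
  if (any(composition <= 0)) {
    abort("element counts must be positive", class = "fs_invalid")
  }
  if (!is.numeric(mass_density) || mass_density <= 0) {
    abort("`mass_density` must be positive (g cm^-3)", class = "fs_invalid")
  }
  structure(list(composition = composition, mass_density = mass_density),
            class = "sld_spec")
}

# Bound coherent scattering lengths, fm (NIST neutron data: Sears 1992)
coherent_b_fm <- c(H = -3.739, D = 6.671, C = 6.646, N = 9.36, O = 5.803)

# Atomic masses, g mol^-1 (D = 2H)
atomic_mass_g <- c(H = 1.008, D = 2.014102, C = 12.011, N = 14.007,
                   O = 15.9994)

avogadro <- 6.02214076e23

#' @param spec An [sld_spec()].
#' @rdname sld_spec
#' @export
sld <- function(spec) {
  stopifnot(inherits(spec, "sld_spec"))
  el <- names(spec$composition)
  sum_b_fm <- sum(spec$composition * coherent_b_fm[el])
  molar_mass <- sum(spec$composition * atomic_mass_g[el])
  n_per_nm3 <- spec$mass_density * avogadro / molar_mass * 1e-21
  n_per_nm3 * sum_b_fm * 1e-6        # fm -> nm
}

#' Common solvent and particle compositions
#'
#' Convenience [sld_spec()] constructors: light water, heavy water and
#' crystalline cellulose (anhydroglucose unit C6H10O5).
#'
#' @param density Mass density in g cm^-3 (defaults: 0.997 for H2O, 1.105
#'   for D2O, 1.6 for crystalline cellulose).
#' @return An [sld_spec()].
#' @export
water_h2o <- function(density = 0.997) sld_spec(c(H = 2, O = 1), density)

#' @rdname water_h2o
#' @export
water_d2o <- function(density = 1.105) sld_spec(c(D = 2, O = 1), density)

#' @rdname water_h2o
#' @export
cellulose_spec <- function(density = 1.6) {
  sld_spec(c(C = 6, H = 10, O = 5), density)
}

#' Contrast-match D2O fraction
#'
#' The volume fraction `f` of D2O in a D2O:H2O mixture whose SLD equals the
#' particle's: `f = (SLD_p - SLD_H) / (SLD_D - SLD_H)`, assuming linear
#' mixing. A value outside `[0, 1]` is returned as computed with a warning
#' (no physical mixture matches).
#'
#' @param particle,solvent_h,solvent_d [sld_spec()]s for the particle and the
#'   two pure solvents.
#' @return The match fraction.
#' @export
#' @examples
#' contrast_match_fraction(cellulose_spec())   # ~0.35
contrast_match_fraction <- function(particle,
                                    solvent_h = water_h2o(),
                                    solvent_d = water_d2o()) {
  sh <- sld(solvent_h); sd_ <- sld(solvent_d)
  if (sh == sd_) {
    abort("solvent SLDs are identical; match fraction undefined",
          class = "fs_invalid")
  }
  f <- (sld(particle) - sh) / (sd_ - sh)
  if (f < 0 || f > 1) {
    warn(sprintf("match fraction %.3f lies outside [0, 1]", f))
  }
  f
}

#' Squared contrast between a particle and a solvent mixture
#'
#' `(delta rho)^2` between the particle SLD and the linearly mixed
#' D2O/H2O SLD at the given D2O volume fraction. A parabola in the fraction
#' with its single root exactly at [contrast_match_fraction()].
#'
#' @param fraction D2O volume fraction(s) in `[0, 1]`.
#' @inheritParams contrast_match_fraction
#' @return Squared SLD difference(s), nm^-4.
#' @export
contrast_factor <- function(fraction, particle = cellulose_spec(),
                            solvent_h = water_h2o(),
                            solvent_d = water_d2o()) {
  if (any(fraction < 0 | fraction > 1)) {
    abort("`fraction` must lie in [0, 1]", class = "fs_invalid")
  }
  mix <- fraction * sld(solvent_d) + (1 - fraction) * sld(solvent_h)
  (sld(particle) - mix)^2
}
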