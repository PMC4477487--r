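#' Monoclinic hk0 lattice
#'
#' The two-dimensional oblique cell describing the cross-section of the
#' cellulose I-beta lattice: axes `a` and `b` (nm) separated by the
#' monoclinic angle `gamma` (degrees). All equatorial (hk0) d-spacings
#' follow from these three numbers.
#'
#' @param a,b Cell axes in nm, > 0.
#' @param gamma Monoclinic angle in degrees, in (80, 110).
#' @return A `monoclinic_cell` object.
#' @export
#' @examples
#' monoclinic_cell(0.778, 0.820, 96.5)   # the reference I-beta cell
monoclinic_cell <- function(a, b, gamma) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0) {
    abort("cell axes must be positive", class = "fs_invalid")
  }
  if (gamma <= 80 || gamma >= 110) {
    abort("`gamma` must lie in (80, 110) degrees", class = "fs_invalid")
  }
  structure(list(a = a, b = b, gamma = gamma), class = "monoclinic_cell")
}

#' @export
print.monoclinic_cell <- function(x, ...) {
  cat(sprintf("<monoclinic_cell: a = %.4f nm, b = %.4f nm, gamma = %.2f deg>\n",
              x$a, x$b, x$gamma))
  invisible(x)
}

#' Reference cellulose I-beta cell
#'
#' The literature I-beta hk0 cell (a = 0.778 nm, b = 0.820 nm,
#' gamma = 96.5 deg) used as the reference for chain-packing areas.
#'
#' @return A [monoclinic_cell()].
#' @export
cellulose_ibeta_cell <- function() monoclinic_cell(0.778, 0.820, 96.5)

#' hk0 d-spacing of an oblique lattice
#'
#' `1/d^2 = (h^2/a^2 + k^2/b^2 - 2 h k cos(gamma)/(a b)) / sin^2(gamma)`.
#'
#' @param cell A [monoclinic_cell()].
#' @param h,k Miller indices (vectors allowed), not both zero.
#' @return d-spacings in nm.
#' @export
#' @examples
#' d_spacing(cellulose_ibeta_cell(), 2, 0)    # the intersheet spacing
d_spacing <- function(cell, h, k) {
  stopifnot(inherits(cell, "monoclinic_cell"))
  if (any(h == 0 & k == 0)) {
    abort("(h, k) must not be (0, 0)", class = "fs_invalid")
  }
  g <- cell$gamma * pi / 180
  inv_d2 <- (h^2 / cell$a^2 + k^2 / cell$b^2 -
               2 * h * k * cos(g) / (cell$a * cell$b)) / sin(g)^2
  1 / sqrt(inv_d2)
}

#' Equatorial reflection table for a cell
#'
#' d-spacings and peak positions `q0 = 2 pi / d` for the principal hk0
#' reflections.
#'
#' @param cell A [monoclinic_cell()].
#' @param reflections Character vector of reflection labels among
#'   `"1-10"`, `"110"`, `"200"`, `"400"`, `"100"`.
#' @return A tibble with columns `hkl`, `h`, `k`, `d`, `q0`.
#' @export
cell_reflections <- function(cell,
                             reflections = c("1-10", "110", "200", "400", "100")) {
  idx <- reflection_indices()
  reflections <- match.arg(reflections, names(idx), several.ok = TRUE)
  hk <- idx[reflections]
  d <- vapply(hk, function(p) d_spacing(cell, p[1], p[2]), 0)
  tibble(hkl = reflections,
         h = vapply(hk, `[`, 0, 1), k = vapply(hk, `[`, 0, 2),
         d = unname(d), q0 = 2 * pi / unname(d))
}

reflection_indices <- function() {
  list("1-10" = c(1, -1), "110" = c(1, 1), "200" = c(2, 0),
       "400" = c(4, 0), "100" = c(1, 0))
}

#' Invert three equatorial d-spacings to a monoclinic cell
#'
#' Recovers the unique cell (reporting convention `gamma >= 90` deg, which
#' pairs with `d(1-10) >= d(110)`) whose hk0 spacings reproduce the three
#' inputs. Exact closed-form inversion; [d_spacing()] of the result
#' round-trips the inputs to machine precision.
#'
#' @param d_1m10,d_110,d_200 d-spacings in nm of the 1-10, 110 and 200
#'   reflections, with `d_1m10 >= d_110`.
#' @return A [monoclinic_cell()].
#' @export
invert_cell <- function(d_1m10, d_110, d_200) {
  if (any(c(d_1m10, d_110, d_200) <= 0)) {
    abort("d-spacings must be positive", class = "fs_invalid")
  }
  if (d_1m10 < d_110) {
    abort(paste("d(1-10) < d(110): violates the gamma >= 90 deg reporting",
                "convention; swap the assignments"),
          class = "fs_inversion")
  }
  # Linear system in A = 1/(a^2 s), B = 1/(b^2 s), C = cos(g)/(a b s),
  # s = sin^2(gamma)
  A <- 1 / (4 * d_200^2)
  B <- (1 / d_110^2 + 1 / d_1m10^2) / 2 - A
  C <- (1 / d_1m10^2 - 1 / d_110^2) / 4
  if (B <= 0) {
    abort("inconsistent d-spacings: implied 1/b^2 is not positive",
          class = "fs_inversion")
  }
  cosg <- C / sqrt(A * B)
  if (abs(cosg) >= 1) {
    abort("inconsistent d-spacings: implied |cos(gamma)| >= 1",
          class = "fs_inversion")
  }
  gamma <- acos(cosg) * 180 / pi
  s <- 1 - cosg^2
  monoclinic_cell(a = 1 / sqrt(A * s), b = 1 / sqrt(B * s), gamma = gamma)
}

#' Microfibril cross-section envelope
#'
#' @param height Dimension perpendicular to the sheets of chains
#'   (the \[200\] stacking direction), nm.
#' @param width Dimension across the sheets, nm.
#' @param shape `"rectangle"` or `"ellipse"` (axes `height` x `width`).
#' @return A `microfibril_envelope` object.
#' @export
microfibril_envelope <- function(height, width,
                                 shape = c("rectangle", "ellipse")) {
  shape <- match.arg(shape)
  if (height <= 0 || width <= 0) {
    abort("envelope dimensions must be positive", class = "fs_invalid")
  }
  structure(list(height = height, width = width, shape = shape),
            class = "microfibril_envelope")
}

envelope_area <- function(envelope) {
  switch(envelope$shape,
         rectangle = envelope$height * envelope$width,
         ellipse = pi * envelope$height * envelope$width / 4)
}

#' Cross-sectional area per cellulose chain
#'
#' The hk0 cell holds two chains, so one chain occupies
#' `a b sin(gamma) / 2` of cross-section. `scale_chain_area()` rescales the
#' reference-cell area by the ratio of an observed intersheet spacing d200 to
#' the reference one, as appropriate when only the 200 spacing of a sample is
#' known precisely.
#'
#' @param cell A [monoclinic_cell()].
#' @return A `chain_packing` object with fields `area_per_chain` (nm^2) and
#'   `source`.
#' @export
#' @examples
#' chain_area(cellulose_ibeta_cell())                      # ~0.32 nm^2
#' scale_chain_area(cellulose_ibeta_cell(), 0.403)         # ~0.33 nm^2
chain_area <- function(cell) {
  stopifnot(inherits(cell, "monoclinic_cell"))
  area <- cell$a * cell$b * sin(cell$gamma * pi / 180) / 2
  new_chain_packing(area, "reference-cell")
}

#' @param reference_cell A [monoclinic_cell()] providing the reference
#'   packing.
#' @param observed_d200 Observed intersheet spacing in nm, > 0.
#' @rdname chain_area
#' @export
scale_chain_area <- function(reference_cell, observed_d200) {
  if (observed_d200 <= 0) {
    abort("`observed_d200` must be positive", class = "fs_invalid")
  }
  ref <- chain_area(reference_cell)
  area <- ref$area_per_chain * observed_d200 /
    d_spacing(reference_cell, 2, 0)
  new_chain_packing(area, "scaled")
}

new_chain_packing <- function(area, source) {
  if (area <= 0.25 || area >= 0.45) {
    warn(sprintf("area per chain %.3f nm^2 is outside the plausible 0.25-0.45 nm^2 range",
                 area))
  }
  structure(list(area_per_chain = area, source = source),
            class = "chain_packing")
}

#' @export
print.chain_packing <- function(x, ...) {
  cat(sprintf("<chain_packing: %.4f nm^2 per chain (%s)>\n",
              x$area_per_chain, x$source))
  invisible(x)
}

#' Number of whole chains fitting in a microfibril envelope
#'
#' "Allow space for" semantics: the envelope cross-section area divided by the
#' per-chain area, rounded down.
#'
#' @param envelope A [microfibril_envelope()].
#' @param packing A `chain_packing` from [chain_area()] or
#'   [scale_chain_area()].
#' @return Integer chain count.
#' @export
#' @examples
#' count_chains(microfibril_envelope(3.8, 3.0),
#'              scale_chain_area(cellulose_ibeta_cell(), 0.403))
count_chains <- function(envelope, packing) {
  stopifnot(inherits(envelope, "microfibril_envelope"),
            inherits(packing, "chain_packing"))
  as.integer(floor(envelope_area(envelope) / packing$area_per_chain))
}
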