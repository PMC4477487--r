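test_that("generators are bit-identical under a fixed seed", {
  tr <- bamboo_truth(seed = 9)
  expect_identical(generate_equatorial_waxs(tr)$intensity,
                   generate_equatorial_waxs(tr)$intensity)
  expect_identical(generate_azimuthal(tr)$intensity,
                   generate_azimuthal(tr)$intensity)
  expect_identical(generate_sans(tr, 0.1)$intensity,
                   generate_sans(tr, 0.1)$intensity)
  expect_identical(generate_pattern_grid(tr, seq(5, 35, 1),
                                         seq(-90, 90, 10))$intensity,
                   generate_pattern_grid(tr, seq(5, 35, 1),
                                         seq(-90, 90, 10))$intensity)
  w1 <- generate_wans_pair(tr); w2 <- generate_wans_pair(tr)
  expect_identical(w1$d$intensity, w2$d$intensity)
  expect_identical(w1$d_meridional$intensity, w2$d_meridional$intensity)
  # different seeds differ
  expect_false(identical(generate_equatorial_waxs(tr)$intensity,
                         generate_equatorial_waxs(tr, seed = 10)$intensity))
})

test_that("zero peak heights leave exactly the background", {
  tr <- noiseless_truth(peak_heights = c("1-10" = 0, "110" = 0, "200" = 0,
                                         "400" = 0))
  p <- generate_equatorial_waxs(tr)
  bg <- tr$background
  expect_equal(p$intensity,
               bg[["amplitude"]] * p$q^(-bg[["exponent"]]) + bg[["constant"]],
               tolerance = 1e-14)
})

test_that("generated 200/400 integral breadths follow the broadening law", {
  # isolate each reflection and measure area/height numerically
  for (hkl in c("200", "400")) {
    h <- c("1-10" = 0, "110" = 0, "200" = 0, "400" = 0)
    h[hkl] <- 1
    tr <- noiseless_truth(peak_heights = h,
                          background = c(amplitude = 0, exponent = 1,
                                         constant = 0))
    p <- generate_equatorial_waxs(tr, q_grid = seq(5, 40, by = 0.005))
    # the asymmetric augmentation is excluded from the defined breadth, so
    # integrate the high-q half and double it
    q0 <- true_q(hkl)
    sel <- p$q >= q0
    half_area <- sum(p$intensity[sel]) * 0.005 -
      0.5 * 0.005 * max(p$intensity)
    measured <- 2 * half_area / max(p$intensity)
    d200 <- 0.403
    expected <- 2 * pi / 3.84 + (pi / 2) * 0.036^2 * q0^2 * d200
    expect_equal(measured, expected, tolerance = 5e-3)
  }
  # frozen values of the forward law
  q200 <- 2 * pi / 0.403
  expect_equal(2 * pi / 3.84 + (pi / 2) * 0.036^2 * q200^2 * 0.403, 1.836,
               tolerance = 1e-3)
  expect_equal(2 * pi / 3.84 + (pi / 2) * 0.036^2 * (2 * q200)^2 * 0.403,
               2.434, tolerance = 1e-3)
})

test_that("equatorial generator rejects a grid missing the 400", {
  expect_error(generate_equatorial_waxs(bamboo_truth(),
                                        q_grid = seq(5, 20, 0.02)),
               class = "fs_config")
})

test_that("azimuthal generator produces the configured dual Gaussian", {
  # nearly pure narrow component: fitted FWHM matches the configuration
  tr <- noiseless_truth(orientation = list(narrow_fwhm = 15, wide_fwhm = 60,
                                           narrow_fraction = 0.999,
                                           centre = 0, total_area = 100,
                                           background = 0.5))
  f <- fit_azimuthal(generate_azimuthal(tr))
  expect_equal(f$narrow$fwhm, 15, tolerance = 1e-4)
  expect_lt(f$wide$area / f$narrow$area, 0.01)
  # zero total area -> flat background
  tr0 <- noiseless_truth(orientation = list(narrow_fwhm = 15, wide_fwhm = 60,
                                            narrow_fraction = 0.5,
                                            centre = 0, total_area = 0,
                                            background = 2))
  expect_equal(generate_azimuthal(tr0)$intensity, rep(2, 181))
  # misordered widths rejected
  bad <- bamboo_truth()
  bad$orientation$narrow_fwhm <- 80
  expect_error(generate_azimuthal(bad), class = "fs_config")
  expect_error(generate_azimuthal(bamboo_truth(), angle_grid = seq(0, 90, 1)),
               class = "fs_config")
})

test_that("azimuthal mixture parameters are recovered across seeds", {
  nn <- ww <- numeric(20)
  for (s in 1:20) {
    f <- fit_azimuthal(generate_azimuthal(bamboo_truth(seed = s)))
    nn[s] <- f$narrow$fwhm; ww[s] <- f$wide$fwhm
  }
  expect_true(all(abs(nn - 15) / 15 < 0.05))
  expect_true(all(abs(ww - 60) / 60 < 0.05))
})

test_that("pattern grid marginalises to the equatorial profile", {
  tr <- noiseless_truth()
  g <- generate_pattern_grid(tr, q_grid = seq(5, 35, 0.1),
                             angle_grid = seq(-90, 90, 2))
  marg <- rowSums(g$intensity) * 2       # integrate over angle (deg)
  full <- generate_equatorial_waxs(tr, q_grid = g$q)
  expect_gt(cor(marg, full$intensity), 0.999)
  # any q column is the dual-Gaussian orientation shape by construction
  i200 <- which.min(abs(g$q - true_q("200")))
  f <- fit_azimuthal(azimuthal_profile(g$angle, g$intensity[i200, ]))
  expect_equal(f$narrow$fwhm, 15, tolerance = 0.02)
  expect_equal(f$wide$fwhm, 60, tolerance = 0.02)
})

test_that("SANS generator places the Bragg peak at 2 pi / spacing and scales with contrast", {
  tr <- noiseless_truth()
  p <- generate_sans(tr, 0)
  i_pk <- which.max(p$intensity - (tr$sans_background[["amplitude"]] *
                                     p$q^(-3) + tr$sans_background[["constant"]]))
  expect_equal(p$q[i_pk], 2 * pi / 2.96, tolerance = 0.01)
  expect_equal(2 * pi / 2.96, 2.123, tolerance = 1e-3)
  # at the contrast-match fraction the peak amplitude is zero
  fm <- contrast_match_fraction(cellulose_spec())
  pm <- generate_sans(tr, fm)
  bg <- tr$sans_background
  expect_equal(pm$intensity,
               bg[["amplitude"]] * pm$q^(-bg[["exponent"]]) + bg[["constant"]],
               tolerance = 1e-9)
  # zero amplitude -> exact background even at full contrast
  tr0 <- noiseless_truth(sans_peak_height = 0)
  p0 <- generate_sans(tr0, 1)
  expect_equal(p0$intensity,
               bg[["amplitude"]] * p0$q^(-bg[["exponent"]]) + bg[["constant"]],
               tolerance = 1e-12)
  expect_error(generate_sans(tr, 1.2), class = "fs_invalid")
})

test_that("SANS peak amplitude is a parabola with its root at the match point", {
  fr <- seq(0, 1, 0.05)
  amp <- contrast_factor(fr)
  fm <- contrast_match_fraction(cellulose_spec())
  expect_true(all(amp >= 0))
  expect_equal(contrast_factor(fm), 0, tolerance = 1e-20)
  # quadratic in fraction: second differences constant
  d2 <- diff(diff(amp))
  expect_lt(max(abs(d2 - d2[1])), 1e-12 * max(amp))
  # single root
  expect_equal(sum(amp < 1e-12 * max(amp)), 0)  # grid misses the root
  expect_lt(abs(fr[which.min(amp)] - fm), 0.05)
})

test_that("WANS pair shares positions, scales heights, and gates 00l on deuteration", {
  tr <- noiseless_truth()
  w <- generate_wans_pair(tr)
  # unchanged positions: D equals H with per-reflection height scaling only
  peaks <- truth_peak_table(tr)
  dp <- difference_profile(w$d, w$h, normalisation = "none")
  i_neg <- which.min(dp$delta_intensity)
  expect_lt(dp$delta_intensity[i_neg], 0)
  expect_equal(dp$q[i_neg], true_q("1-10"), tolerance = 0.05)
  # meridional 00l only in the D form
  expect_equal(2 * pi * 1:2 / 1.038, c(6.053, 12.106), tolerance = 1e-3)
  i1 <- which.min(abs(w$d_meridional$q - 6.053))
  bgl <- tr$background
  base <- bgl[["amplitude"]] * w$d_meridional$q^(-bgl[["exponent"]]) +
    bgl[["constant"]]
  expect_gt(w$d_meridional$intensity[i1] - base[i1], 0.25)
  expect_equal(w$h_meridional$intensity, base, tolerance = 1e-12)
  # all-ones deuteration scale -> difference identically zero (noiseless)
  tr1 <- noiseless_truth(deuteration_scale = c("1-10" = 1, "110" = 1,
                                               "200" = 1, "400" = 1,
                                               "100" = 1))
  w1 <- generate_wans_pair(tr1)
  d1 <- difference_profile(w1$d, w1$h, normalisation = "none")
  expect_equal(max(abs(d1$delta_intensity)), 0, tolerance = 1e-14)
  # missing required scales rejected
  bad <- bamboo_truth(); bad$deuteration_scale <- c("110" = 1)
  expect_error(generate_wans_pair(bad), class = "fs_config")
})

test_that("ground_truth validates its invariants", {
  expect_error(ground_truth(column_length_200 = -1), class = "fs_config")
  expect_error(ground_truth(disorder_g = 0.3), class = "fs_config")
  expect_error(ground_truth(noise_fraction = -0.1), class = "fs_config")
  expect_error(monoclinic_cell(0.8, 0.8, 120), class = "fs_invalid")
  bad_ori <- list(narrow_fwhm = 15, wide_fwhm = 60, narrow_fraction = 1.2,
                  centre = 0, total_area = 1, background = 0)
  expect_error(ground_truth(orientation = bad_ori), class = "fs_config")
})
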