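test_that("absorption_factor has the right limits and monotonicity", {
  s <- cuboid_sample(0.1, width = 1.5, mu = 1)
  expect_equal(absorption_factor(s, 0), exp(-0.1), tolerance = 1e-9)
  expect_equal(absorption_factor(cuboid_sample(0.1, mu = 0), c(0, 30, 60)),
               c(1, 1, 1))
  # decreasing in mu and thickness
  mus <- seq(0.5, 5, 0.5)
  f_mu <- vapply(mus, function(m) {
    absorption_factor(cuboid_sample(0.1, width = 2, mu = m), 40)
  }, 0)
  expect_true(all(diff(f_mu) < 0))
  ts <- seq(0.05, 0.4, 0.05)
  f_t <- vapply(ts, function(t) {
    absorption_factor(cuboid_sample(t, width = 5, mu = 2), 40)
  }, 0)
  expect_true(all(diff(f_t) < 0))
  expect_true(all(f_mu > 0 & f_mu <= 1))
  expect_error(absorption_factor(s, 95), class = "fs_invalid")
  # exit through a side face is refused
  expect_error(absorption_factor(cuboid_sample(1, width = 0.5, mu = 1), 60),
               class = "fs_geometry")
})

test_that("absorption quadrature matches a Monte-Carlo path oracle", {
  withr::with_seed(99, {
    for (i in 1:10) {
      t <- runif(1, 0.05, 0.5)
      mu <- runif(1, 0.2, 3)
      tt <- runif(1, 5, 70)
      s <- cuboid_sample(t, width = 10, mu = mu)
      quad <- absorption_factor(s, tt)
      x <- runif(2e5, 0, t)
      mc <- mean(exp(-mu * (x + (t - x) / cos(tt * pi / 180))))
      expect_equal(quad, mc, tolerance = 2e-3)
    }
  })
  # worked case at mu t = 0.5, 60 degrees, to 3 decimals
  s <- cuboid_sample(0.5, width = 3, mu = 1)
  quad <- absorption_factor(s, 60)
  withr::with_seed(1, {
    x <- runif(1e6, 0, 0.5)
    mc <- mean(exp(-(x + (0.5 - x) / cos(pi / 3))))
  })
  expect_equal(round(quad, 3), round(mc, 3))
})

test_that("correct_absorption inverts a known attenuation", {
  s <- cuboid_sample(0.1, width = 1.5, mu = 1)
  w <- generate_wans_pair(noiseless_truth())
  h <- crop_q(w$h, 5, 34)
  fac <- absorption_factor(s, q_to_two_theta(h$q, 0.242))
  attenuated <- h
  attenuated$intensity <- h$intensity * fac
  corr <- correct_absorption(attenuated, s)
  expect_rel_equal(corr$intensity, h$intensity, 1e-6)
  # mu = 0 is the identity
  c0 <- correct_absorption(h, cuboid_sample(0.1, mu = 0))
  expect_equal(c0$intensity, h$intensity)
  # double correction is refused
  expect_error(correct_absorption(corr, s), class = "fs_config")
  # missing wavelength is refused
  bare <- radial_profile(5:40, rep(1, 36))
  expect_error(correct_absorption(bare, s), class = "fs_config")
})

test_that("difference_profile subtracts on the common grid with sign D - H", {
  w <- generate_wans_pair(noiseless_truth())
  d0 <- difference_profile(w$h, w$h, normalisation = "none")
  expect_equal(max(abs(d0$delta_intensity)), 0)
  # antisymmetry under swapping inputs
  dp <- difference_profile(w$d, w$h, normalisation = "none")
  pd <- difference_profile(w$h, w$d, normalisation = "none")
  expect_equal(dp$delta_intensity, -pd$delta_intensity, tolerance = 1e-14)
  # negative extremum at the 1-10, positive at the 200
  expect_equal(dp$q[which.min(dp$delta_intensity)], true_q("1-10"),
               tolerance = 0.05)
  expect_equal(dp$q[which.max(dp$delta_intensity)], true_q("200"),
               tolerance = 0.05)
  # disjoint ranges are refused
  a <- radial_profile(1:10, rep(1, 10))
  b <- radial_profile(20:30, rep(1, 11))
  expect_error(difference_profile(a, b), class = "fs_invalid")
})

test_that("difference lobe fitting localises the 1-10 when only it is suppressed", {
  tr <- bamboo_truth(deuteration_scale = c("1-10" = 0.5, "110" = 1,
                                           "200" = 1.1, "400" = 1,
                                           "100" = 1))
  for (s in c(2, 8, 14)) {
    w <- generate_wans_pair(ground_truth(seed = s,
                                         deuteration_scale = tr$deuteration_scale))
    lobe <- locate_difference_lobe(difference_profile(w$d, w$h))
    expect_equal(lobe$q0, true_q("1-10"), tolerance = 0.005 * true_q("1-10"))
    expect_lt(lobe$depth, 0)
  }
  # under the default scales the 110's own dip biases the single-lobe
  # estimate; the bias stays below 1%
  w2 <- generate_wans_pair(bamboo_truth(seed = 4))
  lobe2 <- locate_difference_lobe(difference_profile(w2$d, w2$h))
  expect_equal(lobe2$q0, true_q("1-10"), tolerance = 0.01 * true_q("1-10"))
})

test_that("check_equatorial_consistency compares shared reflections", {
  p <- generate_equatorial_waxs(noiseless_truth())
  f1 <- fit_equatorial(p, overlap_width_ratio = 1.5)
  same <- check_equatorial_consistency(f1, f1)
  expect_true(attr(same, "pass"))
  expect_equal(max(same$rel_diff), 0)
  # a 2% shift of d200 fails and names the 200
  f2 <- f1
  f2$components$q0[f2$components$hkl == "200"] <-
    f2$components$q0[f2$components$hkl == "200"] / 1.02
  f2$components$d <- 2 * pi / f2$components$q0
  shifted <- check_equatorial_consistency(f1, f2)
  expect_false(attr(shifted, "pass"))
  expect_true("200" %in% shifted$hkl[!shifted$within])
  # a synthetic H/D pair from one ground truth passes on the well-determined
  # reflections
  w <- generate_wans_pair(bamboo_truth(seed = 6))
  hf <- fit_equatorial(w$h, overlap_width_ratio = 1.5)
  df <- fit_equatorial(w$d, overlap_width_ratio = 1.5)
  cons <- check_equatorial_consistency(hf, df,
                                       reflections = c("200", "400"))
  expect_true(attr(cons, "pass"))
})

test_that("joint H/D fitting recovers the shared lattice and deuteration scales", {
  w <- generate_wans_pair(noiseless_truth())
  pf <- fit_equatorial_pair(w$h, w$d)
  expect_equal(pf$cell$gamma, 92, tolerance = 1e-6)
  expect_equal(pf$components$deuteration_scale,
               c(0.5, 0.9, 1.1, 1, 1), tolerance = 1e-6)
  # with noise the angle stays near truth
  gams <- vapply(c(3, 9), function(s) {
    w <- generate_wans_pair(bamboo_truth(seed = s))
    fit_equatorial_pair(w$h, w$d)$cell$gamma
  }, 0)
  expect_true(all(abs(gams - 92) < 1))
})

test_that("detect_meridional finds 00l peaks only in the deuterated form", {
  w <- generate_wans_pair(bamboo_truth(seed = 5))
  md <- difference_profile(w$d_meridional, w$h_meridional,
                           normalisation = "none")
  det <- suppressWarnings(detect_meridional(md, 1.038))
  hit <- det[det$detected, ]
  expect_setequal(hit$l, c(1, 2))
  expect_equal(hit$q_found[hit$l == 1], 2 * pi / 1.038, tolerance = 0.02)
  expect_equal(hit$q_found[hit$l == 2], 4 * pi / 1.038, tolerance = 0.02)
  # H form differenced against itself: nothing to detect
  null_diff <- difference_profile(w$h_meridional, w$h_meridional,
                                  normalisation = "none")
  w2 <- generate_wans_pair(bamboo_truth(seed = 15))
  h_only <- difference_profile(w$h_meridional, w2$h_meridional,
                               normalisation = "none")
  det_h <- suppressWarnings(detect_meridional(h_only, 1.038, orders = 1:2))
  expect_false(any(det_h$detected))
  # a threshold above the peak significance suppresses detection
  det_hi <- suppressWarnings(
    detect_meridional(md, 1.038, threshold_sigma = 1e6))
  expect_false(any(det_hi$detected))
})
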