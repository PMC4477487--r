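test_that("asymmetric_200 matches its printed definition", {
  q0 <- 15.6; sigma <- 0.73; h <- 2.3
  expect_equal(asymmetric_200(q0, q0, sigma, h), h)
  g <- gaussian_peak(q0 - 1, q0, sigma, h)
  expect_equal(asymmetric_200(q0 - 1, q0, sigma, h), 1.1 * g)
  expect_equal(asymmetric_200(q0 + 1, q0, sigma, h),
               gaussian_peak(q0 + 1, q0, sigma, h))
  expect_error(asymmetric_200(q0, q0, -1, h), class = "fs_invalid")
})

test_that("asymmetric augmentation only ever adds intensity on the low-q side", {
  withr::with_seed(7, {
    for (i in 1:25) {
      q0 <- runif(1, 10, 20); sigma <- runif(1, 0.3, 2)
      h <- runif(1, 0.1, 5)
      q <- seq(q0 - 6 * sigma, q0 + 6 * sigma, length.out = 400)
      f <- asymmetric_200(q, q0, sigma, h)
      f0 <- gaussian_peak(q, q0, sigma, h)
      expect_true(all(f[q < q0] >= f0[q < q0]))
      expect_true(all(f[q >= q0] == f0[q >= q0]))
      # excess integral is strictly positive
      excess <- integrate(function(x) asymmetric_200(x, q0, sigma, h) -
                            gaussian_peak(x, q0, sigma, h),
                          q0 - 12 * sigma, q0)$value
      expect_gt(excess, 0)
    }
  })
})

test_that("integral breadth is sigma * sqrt(2 pi), matching quadrature", {
  expect_equal(integral_breadth(1), 2.5066, tolerance = 1e-4)
  expect_equal(integral_breadth(0.73), 1.830, tolerance = 1e-3)
  for (sigma in c(0.25, 0.73, 1.4)) {
    quad <- integrate(function(x) gaussian_peak(x, 0, sigma, 1),
                      -60 * sigma, 60 * sigma, rel.tol = 1e-13)$value
    expect_equal(integral_breadth(sigma), quad, tolerance = 1e-10)
  }
})

test_that("separate_size_disorder inverts the broadening law", {
  # forward-constructed from delta_q0 = 2 pi / 3.84 and g = 0.036
  q200 <- 2 * pi / 0.403
  law <- function(q) 2 * pi / 3.84 + (pi / 2) * 0.036^2 * q^2 * 0.403
  pts <- data.frame(hkl = c("200", "400"), q0 = c(q200, 2 * q200),
                    d = 0.403, delta_q = law(c(q200, 2 * q200)))
  br <- separate_size_disorder(pts)
  expect_equal(br$L, 3.84, tolerance = 1e-12)
  expect_equal(br$g, 0.036, tolerance = 1e-12)
  expect_equal(br$delta_q0, 2 * pi / br$L, tolerance = 1e-15)
  expect_equal(br$slope, (pi / 2) * br$g^2, tolerance = 1e-15)

  # equal widths at different q: zero disorder limit
  flat <- data.frame(q0 = c(10, 20), d = 0.4, delta_q = c(1.5, 1.5))
  b2 <- separate_size_disorder(flat)
  expect_identical(b2$g, 0)
  expect_equal(b2$L, 2 * pi / 1.5, tolerance = 1e-12)

  # three collinear points agree with any pair
  pts3 <- data.frame(q0 = c(q200, 1.5 * q200, 2 * q200), d = 0.403,
                     delta_q = law(c(q200, 1.5 * q200, 2 * q200)))
  b3 <- separate_size_disorder(pts3)
  expect_equal(b3$L, br$L, tolerance = 1e-9)
  expect_equal(b3$g, br$g, tolerance = 1e-9)

  # degenerate cases
  expect_warning(separate_size_disorder(
    data.frame(q0 = c(10, 20), d = 0.4, delta_q = c(2, 1.5))), "negative")
  expect_error(separate_size_disorder(
    data.frame(q0 = c(10, 20), d = 0.4, delta_q = c(0.1, 3))),
    class = "fs_degenerate")
  expect_error(separate_size_disorder(
    data.frame(q0 = 10, d = 0.4, delta_q = 1)), class = "fs_invalid")
})

test_that("regression agrees with a brute-force grid search", {
  withr::with_seed(11, {
    for (i in 1:8) {
      n <- sample(2:5, 1)
      q0 <- sort(runif(n, 8, 35))
      d <- 0.403
      dq0_true <- runif(1, 1, 2.5)
      slope_true <- runif(1, 5e-4, 4e-3)
      dq <- dq0_true + slope_true * q0^2 * d + rnorm(n, sd = 1e-3)
      pts <- data.frame(q0 = q0, d = d, delta_q = dq)
      br <- separate_size_disorder(pts)
      sse <- function(p) sum((p[1] + p[2] * q0^2 * d - dq)^2)
      opt <- optim(c(dq0_true, slope_true), sse,
                   control = list(reltol = 1e-15, maxit = 5000))
      expect_equal(br$delta_q0, opt$par[1], tolerance = 1e-6)
      expect_equal(br$slope, opt$par[2], tolerance = 1e-6)
    }
  })
})

test_that("subtract_background recovers a known power-law baseline", {
  # pure baseline in: output is (near) zero everywhere
  q <- seq(5, 35, 0.02)
  base <- 4 * q^(-1.3) + 0.4
  p <- radial_profile(q, base)
  out <- subtract_background(p)
  expect_lt(max(abs(out$intensity)), 1e-6)
  # a peak on the baseline: peak area preserved within 2%
  peak <- gaussian_peak(q, 15.6, 0.75, 1)
  p2 <- radial_profile(q, base + peak)
  out2 <- subtract_background(p2)
  area <- sum(out2$intensity[q > 12 & q < 19]) * 0.02
  expect_equal(area, 0.75 * sqrt(2 * pi), tolerance = 0.02)
  # near-idempotence
  out3 <- subtract_background(out2)
  expect_lt(max(abs(out3$intensity - out2$intensity)),
            0.01 * max(base))
  # configuration errors
  expect_error(subtract_background(p2, anchor_windows = list(c(5, 6.5))),
               class = "fs_config")
  expect_error(subtract_background(p2, anchor_windows = list(c(5, 6.5),
                                                             c(40, 50))),
               class = "fs_config")
  # metadata records the model and anchors
  expect_identical(profile_meta(out2)$background$anchors,
                   list(c(5, 6.5), c(33.5, 35)))
})

test_that("fit_azimuthal separates narrow and wide orientation components", {
  # degenerate single-Gaussian input
  tr <- noiseless_truth(orientation = list(narrow_fwhm = 15, wide_fwhm = 60,
                                           narrow_fraction = 0.999,
                                           centre = 0, total_area = 50,
                                           background = 1))
  f <- fit_azimuthal(generate_azimuthal(tr))
  expect_equal(f$narrow$fwhm, 15, tolerance = 0.01)
  expect_lt(f$wide$area, 0.01 * f$narrow$area)
  expect_true(f$converged)
  expect_lt(f$narrow$fwhm, f$wide$fwhm)
  # flat input: zero-area components, background carries the level
  flat <- azimuthal_profile(seq(-90, 90, 2), rep(3, 91))
  ff <- fit_azimuthal(flat)
  expect_lt(ff$narrow$area + ff$wide$area, 1e-6)
  expect_equal(ff$background, 3, tolerance = 1e-6)
  expect_error(fit_azimuthal(azimuthal_profile(1:10, rep(1, 10))),
               class = "fs_invalid")
})

test_that("fit_equatorial recovers a noiseless pattern essentially exactly", {
  p <- generate_equatorial_waxs(noiseless_truth())
  fit <- fit_equatorial(p, overlap_width_ratio = 1.5)
  truth_tab <- truth_peak_table(noiseless_truth())
  m <- merge(fit$components, truth_tab, by = "hkl")
  expect_true(all(abs(m$q0.x - m$q0.y) / m$q0.y < 0.002))
  d200 <- fit$components$d[fit$components$hkl == "200"]
  expect_equal(d200, 0.403, tolerance = 1e-4)
  expect_equal(round(d200, 3), 0.403)
  # ordering constraint holds structurally
  q0s <- fit$components$q0[match(c("1-10", "110", "200", "400"),
                                 fit$components$hkl)]
  expect_true(all(diff(q0s) > 0))
  expect_error(fit_equatorial(crop_q(p, 10, 20)), class = "fs_invalid")
})

test_that("an absent 400 collapses to a zero-area component", {
  tr <- noiseless_truth(peak_heights = c("1-10" = 0.45, "110" = 0.55,
                                         "200" = 1, "400" = 0, "100" = 0.04))
  fit <- fit_equatorial(generate_equatorial_waxs(tr),
                        overlap_width_ratio = 1.5)
  comp <- fit$components
  expect_lt(comp$area[comp$hkl == "400"], 1e-6)
  expect_equal(comp$q0[comp$hkl == "200"], true_q("200"), tolerance = 0.01)
  expect_equal(comp$height[comp$hkl == "200"], 1, tolerance = 0.01)
})

test_that("reconstruct_equatorial extracts the oriented narrow component", {
  tr <- noiseless_truth()
  g <- generate_pattern_grid(tr, q_grid = seq(5, 35, 0.2),
                             angle_grid = seq(-90, 90, 3))
  rec <- reconstruct_equatorial(g)
  peaks <- truth_peak_table(tr)
  oriented <- fibrilscatter:::equatorial_model(rec$q, peaks)
  expect_gt(cor(rec$intensity, oriented), 0.995)
  expect_length(profile_meta(rec)$failed_columns, 0)
  # zero wide component: reconstruction is proportional to the plain cut
  tr2 <- noiseless_truth(orientation = list(narrow_fwhm = 15, wide_fwhm = 60,
                                            narrow_fraction = 0.999,
                                            centre = 0, total_area = 100,
                                            background = 0.5))
  g2 <- generate_pattern_grid(tr2, q_grid = seq(5, 35, 0.5),
                              angle_grid = seq(-90, 90, 3))
  rec2 <- reconstruct_equatorial(g2)
  i_eq <- which.min(abs(g2$angle))
  cut <- g2$intensity[, i_eq]
  expect_gt(cor(rec2$intensity, cut), 0.999)
})

test_that("noiseless end-to-end WAXS recovery is within 1% of truth", {
  res <- analyze_equatorial_waxs(generate_equatorial_waxs(noiseless_truth()))
  expect_equal(res$broadening$L, 3.84, tolerance = 0.01)
  expect_equal(res$broadening$g, 0.036, tolerance = 0.01)
  expect_equal(res$cell$gamma, 92, tolerance = 0.01)
  d200 <- res$equatorial$components$d[res$equatorial$components$hkl == "200"]
  expect_equal(d200, 0.403, tolerance = 0.001)
})
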