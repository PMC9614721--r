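test_that("background correction subtracts pointwise and tracks provenance", {
  mix <- gen_spectrum(rbind(donor_peak, acceptor_peak), label = "mixture")
  bg <- gen_spectrum(data.frame(center_nm = 628, sigma_nm = 20, amp = 10),
                     label = "lectin-only")
  # identity case: correcting a spectrum against itself gives exactly zero
  zero <- correct_spectrum(mix, mix)
  expect_true(all(zero$intensity == 0))
  expect_equal(zero$provenance$background, "mixture")

  # analytic case: donor peak untouched, acceptor peak reduced by the
  # direct-excitation amplitude
  corr <- correct_spectrum(mix, bg)
  wl <- corr$wavelength_nm
  expected <- 100 * exp(-(wl - 550)^2 / (2 * 15^2)) +
    (40 - 10) * exp(-(wl - 628)^2 / (2 * 20^2))
  expect_equal(corr$intensity, expected, tolerance = 1e-12)

  # mismatched grids refuse to subtract
  short <- emission_spectrum(seq(480, 700, 1),
                             rep(1, length(seq(480, 700, 1))))
  expect_error(correct_spectrum(mix, short), class = "qdfret_grid_mismatch")
  # mismatched excitation is a configuration error
  bg2 <- gen_spectrum(acceptor_peak, excitation_nm = 400)
  expect_error(correct_spectrum(mix, bg2), "excitation")
})

test_that("negative corrected intensities are kept and counted", {
  a <- emission_spectrum(480:500, rep(1, 21), label = "a")
  b <- emission_spectrum(480:500, c(rep(2, 5), rep(0, 16)), label = "b")
  expect_warning(corr <- correct_spectrum(a, b), "5 corrected")
  expect_equal(corr$n_negative, 5)
  expect_equal(min(corr$intensity), -1)
})

test_that("peak extraction matches closed-form Gaussian evaluation", {
  sp <- gen_spectrum(rbind(donor_peak, acceptor_peak), by_nm = 0.5)
  I <- extract_intensities(sp)
  gauss <- function(wl) 100 * exp(-(wl - 550)^2 / (2 * 15^2)) +
    40 * exp(-(wl - 628)^2 / (2 * 20^2))
  expect_equal(unname(I["I_D"]), gauss(550), tolerance = 1e-10)
  expect_equal(unname(I["I_A"]), gauss(628), tolerance = 1e-10)

  # constant spectrum returns the constant at both wavelengths
  flat <- emission_spectrum(480:750, rep(7, 271))
  expect_equal(unname(extract_intensities(flat)), c(7, 7))
  # window mode averages nearby grid points
  Iw <- extract_intensities(sp, window_nm = 2)
  expect_lt(unname(Iw["I_D"]), gauss(550))  # window mean below peak top
  expect_error(extract_intensities(flat, donor_nm = 800), "outside")
})

test_that("the FRET ratio is ratiometric and guards the degenerate donor", {
  expect_equal(fret_ratio(10, 0), 0)
  expect_equal(fret_ratio(4, 10), 2.5)
  expect_error(fret_ratio(0, 5), "degenerate")
  # invariance under common scaling of both channels
  for (s in c(0.01, 1, 37.5)) {
    expect_equal(fret_ratio(4 * s, 10 * s), 2.5)
  }
})

test_that("linearity check fits a line and flags inner-filter risk", {
  conc <- c(1, 2, 3, 4) * 1e-8
  rep <- check_linearity(conc, 5e8 * conc)
  expect_equal(rep$r_squared, 1)
  expect_false(rep$inner_filter_flag)
  rep2 <- check_linearity(conc, 5e8 * conc, absorbance_450 = c(0.001, 0.02))
  expect_true(rep2$inner_filter_flag)
  expect_error(check_linearity(conc[1:2], conc[1:2]), "insufficient")
})

test_that("overlap integral converges to the delta-peak limit", {
  eps <- data.frame(wavelength_nm = seq(480, 750, 0.25), epsilon = 1e5)
  # zero extinction -> zero overlap
  d0 <- gen_spectrum(donor_peak, by_nm = 0.25)
  expect_equal(overlap_integral(d0, transform(eps, epsilon = 0)), 0)
  # narrowing donor peak at 600 nm -> J -> eps * 600^4
  Js <- sapply(c(4, 2, 1, 0.5), function(sig) {
    d <- gen_spectrum(data.frame(center_nm = 600, sigma_nm = sig, amp = 1),
                      by_nm = 0.25)
    overlap_integral(d, eps)
  })
  target <- 1e5 * 600^4
  errs <- abs(Js - target) / target
  expect_true(all(diff(errs) < 0))        # monotone convergence
  expect_lt(errs[length(errs)], 1e-3)
  # disjoint ranges refuse
  far <- data.frame(wavelength_nm = 900:950, epsilon = 1e5)
  expect_error(overlap_integral(d0, far), "overlap")
})

test_that("overlap integral is quadrature-converged on smooth spectra", {
  eps_fun <- function(wl) 1.2e5 * exp(-(wl - 600)^2 / (2 * 30^2))
  mk <- function(by) {
    d <- gen_spectrum(donor_peak, by_nm = by)
    overlap_integral(d, data.frame(wavelength_nm = d$wavelength_nm,
                                   epsilon = eps_fun(d$wavelength_nm)))
  }
  expect_equal(mk(1), mk(0.1), tolerance = 1e-3)
})

test_that("Forster radius follows the sixth-root law", {
  # invert the formula by hand: the sixth-root argument giving R0 = 5.7 nm
  # is (5.7/0.02108)^6 = 3.909e14; with the 62% donor quantum yield the
  # implied overlap integral is J = 2.959e15 M^-1 cm^-1 nm^4
  arg <- (5.7 / 0.02108)^6
  expect_equal(arg, 3.909e14, tolerance = 1e-3)
  J <- arg / ((2 / 3) * 1.33^-4 * 0.62)
  expect_equal(forster_radius(J, 0.62), 5.7, tolerance = 1e-9)
  # scaling law: doubling kappa2 multiplies R0 by 2^(1/6)
  expect_equal(forster_radius(1e15, 0.5, kappa2 = 4 / 3) /
                 forster_radius(1e15, 0.5, kappa2 = 2 / 3),
               2^(1 / 6), tolerance = 1e-12)
  # monotonicity in each argument
  expect_gt(forster_radius(2e15, 0.5), forster_radius(1e15, 0.5))
  expect_gt(forster_radius(1e15, 0.6), forster_radius(1e15, 0.5))
  expect_lt(forster_radius(1e15, 0.5, refractive_index = 1.5),
            forster_radius(1e15, 0.5, refractive_index = 1.33))
  expect_error(forster_radius(0, 0.62), "positive")
})

test_that("fret_pair_spec validates the stated radius against parameters", {
  J <- 4e15
  R0 <- forster_radius(J, 0.62)
  spec <- fret_pair_spec(donor_qy = 0.62, overlap_integral_J = J,
                         forster_radius_R0 = R0)
  expect_equal(spec$forster_radius_R0, R0)
  expect_error(fret_pair_spec(donor_qy = 0.62, overlap_integral_J = J,
                              forster_radius_R0 = R0 * 1.01),
               "inconsistent")
})

test_that("resampling is explicit and refuses extrapolation", {
  sp <- gen_spectrum(donor_peak)
  rs <- resample_spectrum(sp, seq(500, 600, 0.5))
  expect_equal(rs$intensity[rs$wavelength_nm == 550],
               100, tolerance = 1e-6)
  expect_error(resample_spectrum(sp, seq(400, 600, 1)), "outside")
})
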