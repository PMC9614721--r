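test_that("kinetic models obey half-life and saturation identities", {
  # association: zero at t = 0, y_max/2 at t = ln2/(k_on x0), plateau y_max
  k <- 2.24e7; x0 <- 2e-8; ym <- 2.49
  expect_equal(association_model(0, ym, k, x0, 0), 0)
  expect_equal(association_model(0, ym, k, x0, 0, form = "hyperbolic"), 0)
  th <- log(2) / (k * x0)
  expect_equal(association_model(th, ym, k, x0, 0), ym / 2, tolerance = 1e-12)
  expect_equal(association_model(1e5, ym, k, x0, 0), ym, tolerance = 1e-6)
  expect_equal(association_model(1e7, ym, k, x0, 0, form = "hyperbolic"),
               ym, tolerance = 1e-3)
  # both drift-free forms are monotone and bounded by y_max
  t <- seq(0, 60, 0.0125)
  for (fm in c("exponential", "hyperbolic")) {
    y <- association_model(t, ym, k, x0, 0, form = fm)
    expect_true(all(diff(y) > 0))
    expect_true(all(y <= ym))
  }
  # dissociation: y_0 at 0, midpoint at ln2/k_off', y_eq at infinity
  expect_equal(dissociation_model(0, 1.261, 0.129, 3.23, 0), 1.261)
  expect_equal(dissociation_model(log(2) / 3.23, 1.261, 0.129, 3.23, 0),
               (1.261 + 0.129) / 2, tolerance = 1e-12)
  expect_equal(dissociation_model(100, 1.261, 0.129, 3.23, 0), 0.129,
               tolerance = 1e-9)
})

test_that("half-life formulas reproduce the benchmark rate constants", {
  expect_equal(half_life_association(2e-8, 2.24e7), 1.547, tolerance = 0.001)
  expect_equal(half_life_association(2e-8, 2.92e7), 1.187, tolerance = 0.001)
  expect_equal(half_life_dissociation(3.23), 0.2146, tolerance = 0.001)
  expect_equal(half_life_dissociation(0.45), 1.540, tolerance = 0.001)
  expect_error(half_life_association(0, 1e7), "positive")
  expect_error(half_life_dissociation(-1), "positive")
})

test_that("preprocessing corrects, averages and block-smooths channels", {
  # constant channels: 628 = 2, 550 = 4 with zero background -> ratio 0.5
  t <- seq(0, 1, 0.0125)
  mkch <- function(v, nm, role = "sample")
    kinetic_channel(t, rep(v, length(t)), nm, role = role)
  tr <- preprocess_trace(list(mkch(4, 550), mkch(2, 628)),
                         list(mkch(0, 550, "background"),
                              mkch(0, 628, "background")))
  expect_true(all(tr$fret_ratio == 0.5))

  # block smoothing by 5 turns a 0.0125 s grid into 0.0625 s
  t60 <- seq(0, 60, 0.0125)
  mk60 <- function(v, nm, role = "sample")
    kinetic_channel(t60, rep(v, length(t60)), nm, role = role)
  tr5 <- preprocess_trace(list(mk60(4, 550), mk60(2, 628)),
                          list(mk60(0, 550, "background"),
                               mk60(0, 628, "background")),
                          smoothing_block = 5)
  expect_equal(unique(round(diff(tr5$time_s), 10)), 0.0625)

  # background equal to sample zeroes the donor -> degenerate signal
  expect_error(
    preprocess_trace(list(mkch(4, 550), mkch(2, 628)),
                     list(mkch(4, 550, "background"),
                          mkch(0, 628, "background"))),
    "degenerate")
  # grid mismatch
  tshort <- seq(0, 0.5, 0.0125)
  expect_error(
    preprocess_trace(list(mkch(4, 550), mkch(2, 628)),
                     list(kinetic_channel(tshort, rep(0, length(tshort)),
                                          550, role = "background"),
                          mkch(0, 628, "background"))),
    class = "qdfret_grid_mismatch")
})

test_that("noise-free association and dissociation fits are exact", {
  ga <- gen_kinetic_trace("association",
                          list(y_max = 2.49, k_on = 2.24e7, a = 0.0103),
                          x0 = 2e-8, noise_sd = 0)
  tra <- preprocess_trace(ga$sample_channels, ga$background_channels,
                          x0 = 2e-8, direction = "association")
  fa <- fit_association(tra)
  expect_equal(fa$y_max, 2.49, tolerance = 1e-6)
  expect_equal(fa$k_on, 2.24e7, tolerance = 1e-6)
  expect_equal(fa$a, 0.0103, tolerance = 1e-5)
  expect_equal(fa$t_half, log(2) / (2e-8 * fa$k_on), tolerance = 1e-12)
  expect_equal(fa$t_half, 1.55, tolerance = 0.002)
  expect_equal(fa$drift_class, "qd_dimming")

  gd <- gen_kinetic_trace("dissociation",
                          list(y_0 = 1.261, y_eq = 0.129,
                               k_off_prime = 3.23, a = 0.00157),
                          x0 = 2e-8, noise_sd = 0)
  trd <- preprocess_trace(gd$sample_channels, gd$background_channels,
                          x0 = 2e-8, direction = "dissociation")
  fd <- fit_dissociation(trd)
  expect_equal(fd$y_0, 1.261, tolerance = 1e-6)
  expect_equal(fd$y_eq, 0.129, tolerance = 1e-6)
  expect_equal(fd$k_off_prime, 3.23, tolerance = 1e-6)
  expect_equal(fd$a, 0.00157, tolerance = 1e-4)
  expect_equal(fd$t_half, log(2) / fd$k_off_prime, tolerance = 1e-12)
  expect_equal(fd$t_half, 0.215, tolerance = 0.003)
})

test_that("noisy association fit matches the grid-search oracle", {
  g <- gen_kinetic_trace("association",
                         list(y_max = 2.49, k_on = 2.24e7, a = 0.0103),
                         x0 = 2e-8, duration_s = 30, noise_sd = 2,
                         n_replicates = 3, seed = 5)
  tr <- preprocess_trace(g$sample_channels, g$background_channels,
                         x0 = 2e-8, direction = "association")
  f <- fit_association(tr)
  oracle <- grid_search_association(tr, 2e-8,
                                    k_on_range = c(1e7, 5e7),
                                    y_max_range = c(2.2, 2.8),
                                    a_range = c(0, 0.03))
  expect_equal(f$k_on, oracle$k_on, tolerance = 0.05)
  expect_equal(f$y_max, oracle$y_max, tolerance = 0.02)
  expect_lt(abs(f$k_on - 2.24e7), 3 * max(f$k_on_sd, 0.01 * f$k_on))
})

test_that("slow secondary association yields a negative drift constant", {
  # biphasic behavior: main exponential rise plus slow linear increase
  g <- gen_kinetic_trace("association",
                         list(y_max = 0.0532, k_on = 16e7, a = -2.5e-3),
                         x0 = 2e-8, noise_sd = 0)
  tr <- preprocess_trace(g$sample_channels, g$background_channels,
                         smoothing_block = 5, x0 = 2e-8,
                         direction = "association")
  f <- fit_association(tr)
  expect_lt(f$a, 0)
  expect_equal(f$drift_class, "secondary_association")
})

test_that("ratiometric invariance: channel scaling leaves fits unchanged", {
  g <- gen_kinetic_trace("association",
                         list(y_max = 2.49, k_on = 2.24e7, a = 0.0103),
                         x0 = 2e-8, duration_s = 20, noise_sd = 0)
  scale_ch <- function(ch, s) kinetic_channel(
    ch$time_s, ch$intensity * s, attr(ch, "emission_nm"),
    attr(ch, "replicate_id"), attr(ch, "role"))
  tr1 <- preprocess_trace(g$sample_channels, g$background_channels,
                          x0 = 2e-8, direction = "association")
  tr2 <- preprocess_trace(lapply(g$sample_channels, scale_ch, s = 13.7),
                          lapply(g$background_channels, scale_ch, s = 13.7),
                          x0 = 2e-8, direction = "association")
  f1 <- fit_association(tr1); f2 <- fit_association(tr2)
  expect_equal(f1$k_on, f2$k_on, tolerance = 1e-9)
  expect_equal(f1$y_max, f2$y_max, tolerance = 1e-9)
})

test_that("derived rates reconcile kinetics with equilibrium affinity", {
  r1 <- derive_rates(2.24e7, 3.23, 1.54e-9)
  expect_equal(r1$Kd_prime, 1.44e-7, tolerance = 0.002)
  expect_equal(r1$k_off_natural, 0.0345, tolerance = 0.002)
  r2 <- derive_rates(2.92e7, 2.95, 1.62e-9)
  expect_equal(r2$Kd_prime, 1.01e-7, tolerance = 0.002)
  expect_equal(r2$k_off_natural, 0.0473, tolerance = 0.002)
  expect_error(derive_rates(0, 1, 1e-9), "positive")
  # competition caveat: Kd' sits about two orders of magnitude above the
  # equilibrium Kd for the two constructs with well-determined association
  # fits (the weak-binding lectin's k_on is too uncertain to derive from)
  kin <- kinetic_parameter_table()
  aff <- affinity_temperature_table()
  kd20 <- with(aff[aff$temperature_K == 293.15, ],
               stats::setNames(Kd, lectin))
  for (lec in c("DC-SIGN", "DC-SIGN-C")) {
    i <- match(lec, kin$lectin)
    dr <- derive_rates(kin$assoc_k_on_1e7[i] * 1e7,
                       kin$dissoc_k_off_prime[i], kd20[[lec]])
    expect_gt(dr$Kd_prime, 10 * kd20[[lec]])
  }
})

test_that("an upward dissociation trace warns but still fits", {
  t <- seq(0, 10, 0.0125)
  y <- 0.2 + 0.5 * (1 - exp(-0.5 * t))
  tr <- structure(data.frame(time_s = t, fret_ratio = y),
                  x0 = 2e-8, direction = "dissociation",
                  smoothing_block = 1L,
                  class = c("kinetic_trace", "data.frame"))
  expect_warning(fit <- fit_dissociation(tr), "direction mismatch")
  expect_s3_class(fit, "dissociation_fit")
})
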