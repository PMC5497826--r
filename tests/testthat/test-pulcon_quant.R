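# Quantification core: integration, ERETIC factor, concentrations, mass
# fractions, PAH4 and detection limits.

test_that("region integral of a Lorentzian matches the arctan closed form", {
  # fraction of a unit Lorentzian (HWHM g at center c) inside [lo, hi]:
  # (atan((hi-c)/g) + atan((c-lo)/g)) / pi
  g <- 0.0025; ctr <- 1.0
  sp <- lorentz_spectrum(ctr, g)
  regs <- default_regions()
  got <- integrate_region(sp, regs$mosh)
  expected <- (atan((3.0 - ctr) / g) + atan((ctr - 0.2) / g)) / pi
  # water exclusion removes a sliver of tail
  expected <- expected - (atan((1.58 - ctr) / g) - atan((1.50 - ctr) / g)) / pi
  expect_rel_equal(got, expected, 1e-3)
  expect_rel_equal(got, 0.998, 2e-3)
})

test_that("integration is additive over a partition of the aromatic span", {
  sp <- simulate_mineral_oil(10, 0.8, seed = 20, noise_sd = "calibrated",
                             grid = test_grid)
  mk <- function(w) integration_region("w", list(w), ref_compound = "x",
                                       ref_mw = 1, n_protons = 1)
  full <- integrate_region(sp, mk(c(9.20, 6.50)))
  parts <- list(c(9.20, 7.55), c(7.55, 7.50), c(7.50, 7.30), c(7.30, 7.22),
                c(7.22, 7.00), c(7.00, 6.97), c(6.97, 6.50))
  expect_equal(sum(vapply(parts, function(w) integrate_region(sp, mk(w)),
                          numeric(1))),
               full, tolerance = 1e-12)
  # zero spectrum integrates to exactly zero
  z <- sp; z$intensity[] <- 0
  expect_identical(integrate_region(z, mk(c(9, 7))), 0)
})

test_that("integration errors and degenerate windows behave as documented", {
  sp <- lorentz_spectrum(1, 0.01)
  out_of_range <- integration_region("far", list(c(20, 15)),
                                     ref_compound = "x", ref_mw = 1,
                                     n_protons = 1)
  expect_error(integrate_region(sp, out_of_range), "outside spectrum axis")
  hollow <- integration_region("hollow", list(c(2, 1)), list(c(2, 1)),
                               ref_compound = "x", ref_mw = 1, n_protons = 1)
  expect_warning(v <- integrate_region(sp, hollow), "no grid points")
  expect_identical(v, 0)
})

test_that("the ERETIC factor evaluates the calibration formula", {
  # I = 1500 on the ethylbenzene quartet: 1500 * 106.17 / (5 * 2) = 15925.5;
  # a rectangular signal makes the window integral exactly 1500
  regs <- default_regions()
  sp <- lorentz_spectrum(2.645, 0.002, area = 0)
  m <- region_mask(sp, regs$quantref_eb_q)
  sp$intensity[m] <- 1500 / (sum(m) * abs(diff(sp$ppm[1:2])))
  I <- integrate_region(sp, regs$quantref_eb_q)
  factor <- I * 106.17 / (5.0 * 2)
  expect_rel_equal(factor, 15925.5, 1e-9)
})

test_that("a consistent quantref gives four identical factors", {
  er <- local_eretic(101, 0)
  spread <- max(er$per_signal) / min(er$per_signal) - 1
  expect_lt(spread, 1e-6)
  expect_true(er$valid)
  expect_equal(er$value, mean(er$per_signal))
})

test_that("the factor is linear in the spectrum scale", {
  qr <- simulate_quantref(seed = 102, noise_sd = 0, grid = test_grid)
  er1 <- eretic_from_quantref(qr)
  qr2 <- qr; qr2$intensity <- 2 * qr$intensity
  er2 <- eretic_from_quantref(qr2)
  expect_equal(er2$value, 2 * er1$value, tolerance = 1e-12)
})

test_that("inconsistent quantref signals invalidate the factor", {
  qr <- simulate_quantref(seed = 103, noise_sd = 0, grid = test_grid)
  regs <- default_regions()
  m <- region_mask(qr, regs$quantref_tcnb)
  qr$intensity[m] <- qr$intensity[m] * 1.25
  expect_warning(er <- eretic_from_quantref(qr), "spread")
  expect_false(er$valid)
  expect_error(quantify(qr, regs$moah, er), "invalid ERETIC")
  expect_s3_class(quantify(qr, regs$moah, er, force = TRUE), "quant_result")
  # non-positive integral is a calibration error
  qr$intensity[m] <- -abs(qr$intensity[m])
  expect_error(eretic_from_quantref(qr), "calibration error")
})

test_that("calibration and quantification are mutual inverses", {
  er <- local_eretic(101, 0)
  qr <- simulate_quantref(seed = 101, noise_sd = 0, grid = test_grid)
  regs <- default_regions()
  res <- quantify(qr, regs$quantref_eb_q, er)
  expect_rel_equal(res$concentration, 5.0, 1e-9)
  # scale invariance: scaling the whole series leaves concentrations alone
  for (k in c(0.2, 3, 1e4)) {
    qr_k <- qr; qr_k$intensity <- k * qr$intensity
    er_k <- eretic_from_quantref(qr_k)
    res_k <- quantify(qr_k, regs$quantref_eb_q, er_k)
    expect_rel_equal(res_k$concentration, 5.0, 1e-9)
  }
  # zero integral quantifies to zero
  z <- qr; z$intensity[] <- 0
  expect_identical(quantify(z, regs$moah, er)$concentration, 0)
})

test_that("mass fraction conversion follows the dilution arithmetic", {
  res <- structure(list(analyte = "x", absolute_integral = 1,
                        concentration = 100 / 3, raw_concentration = 100 / 3,
                        mass_fraction = NA_real_,
                        lod_mass_fraction = NA_real_, detected = NA),
                   class = "quant_result")
  out <- to_mass_fraction(res, sample_prep(50, 1.5))
  expect_equal(out$mass_fraction, 100, tolerance = 1e-12)
  res$concentration <- 0
  expect_equal(to_mass_fraction(res, sample_prep(50, 1.5))$mass_fraction, 0)
  expect_warning(out2 <- to_mass_fraction(res, NULL), "missing sample preparation")
  expect_true(out2$unconvertible)
})

test_that("a simulated chrysene spike is recovered and formatted", {
  er <- local_eretic(101, 0)
  sp <- simulate_chrysene_reference(0.55, seed = 104, noise_sd = 0,
                                    grid = test_grid)
  pah <- suppressWarnings(quantify_pah4(sp, er, prep50))  # zero-noise LODs
  expect_rel_equal(pah$chrysene$mass_fraction, 0.55, 0.03)
  expect_match(format_mass_fraction(pah$chrysene), "^0\\.5[0-9]$")
})

test_that("a blank matrix reports all PAH4 as n.d. with finite LODs", {
  er <- local_eretic(101, "calibrated")
  sp <- simulate_mineral_oil(100, 0, seed = 105, noise_sd = "calibrated",
                             grid = test_grid)
  pah <- quantify_pah4(sp, er, prep50)
  for (r in pah[c("chrysene", "benzo_a_pyrene", "benz_a_anthracene")]) {
    expect_false(r$detected)
    expect_true(is.finite(r$lod_mass_fraction) && r$lod_mass_fraction > 0)
    expect_match(format_mass_fraction(r), "^n\\.d\\. <")
  }
})

test_that("the 3-sigma detection boundary is inclusive", {
  er <- local_eretic(101, 0)
  regs <- default_regions()
  sp <- lorentz_spectrum(9.16, 0.002, area = 0)   # flat spectrum
  # plant noise of known SD in the noise window, and a peak exactly at 3 sigma
  s <- 1e-3
  m_noise <- sp$ppm <= 10.5 & sp$ppm > 9.5
  vals <- rep(c(-s, s), length.out = sum(m_noise))
  vals <- vals - mean(vals)
  sp$intensity[m_noise] <- vals * (s / stats::sd(vals))
  m_win <- region_mask(sp, regs$benz_a_anthracene)
  sp$intensity[which(m_win)[5]] <- 3 * s
  pah <- quantify_pah4(sp, er, prep50)
  expect_true(pah$benz_a_anthracene$detected)
  sp$intensity[which(m_win)[5]] <- 3 * s * (1 - 1e-9)
  pah2 <- quantify_pah4(sp, er, prep50)
  expect_false(pah2$benz_a_anthracene$detected)
})

test_that("LOD scales inversely with sample mass and vanishes without noise", {
  er <- local_eretic(101, "calibrated")
  sp <- simulate_mineral_oil(100, 0, seed = 106, noise_sd = "calibrated",
                             grid = test_grid)
  regs <- default_regions()
  lod50 <- estimate_lod(sp, regs$chrysene, er, sample_prep(50, 1.5))
  lod25 <- estimate_lod(sp, regs$chrysene, er, sample_prep(25, 1.5))
  expect_equal(lod25, 2 * lod50, tolerance = 1e-12)
  z <- sp; z$intensity[] <- 0
  expect_warning(l0 <- estimate_lod(z, regs$chrysene, er, prep50),
                 "zero noise")
  expect_identical(l0, 0)
})

test_that("mass fractions are linear in the spiked amount", {
  er <- local_eretic(101, 0)
  regs <- default_regions()
  levels <- c(1.01, 2.04, 3.04, 4.05, 5.07)
  measured <- vapply(seq_along(levels), function(i) {
    sp <- simulate_mineral_oil(11.2 * levels[i], levels[i], seed = 200 + i,
                               noise_sd = 0, grid = test_grid)
    to_mass_fraction(quantify(sp, regs$moah, er), prep50)$mass_fraction
  }, numeric(1))
  fit <- stats::lm(measured ~ levels)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 0.999)  # near-perfect fit
})
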