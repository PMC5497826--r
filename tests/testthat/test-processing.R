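# FID processing: Fourier transform, phasing, baseline, referencing.

make_fid <- function(f_hz, decay = 2, n = 8192, sfo = 400.13,
                     sw_ppm = 14, amp = 1) {
  dwell <- 1 / (sfo * sw_ppm)
  t <- (0:(n - 1)) * dwell
  fid_record(amp * complex(real = cos(2 * pi * f_hz * t) * exp(-decay * t),
                           imaginary = sin(2 * pi * f_hz * t) * exp(-decay * t)),
             dwell_time = dwell, spectrometer_freq = sfo, center_ppm = 0)
}

test_that("FT places a decaying cosine at f/sfo ppm", {
  sfo <- 400.13
  fid <- make_fid(2.5 * sfo)
  sp <- fourier_transform(fid, processing_config(line_broadening = 0,
                                                 phase_method = "manual"))
  peak <- sp$ppm[which.max(sp$intensity)]
  expect_lt(abs(peak - 2.5), abs(sp$ppm[2] - sp$ppm[1]))
})

test_that("FT integral matches the closed-form absorptive Lorentzian area", {
  # one-sided decay A*exp(2*pi*i*f*t - R*t): absorption-mode area = A/2 (Hz
  # units), i.e. A/(2*sfo) on the ppm axis; first-point halving removes the
  # DC offset so the window integral equals it
  sfo <- 400.13; A <- 3
  fid <- make_fid(2.5 * sfo, amp = A)
  sp <- fourier_transform(fid, processing_config(line_broadening = 0,
                                                 phase_method = "manual"))
  reg <- integration_region("peak", list(c(3.5, 1.5)),
                            ref_compound = "x", ref_mw = 1, n_protons = 1)
  expect_rel_equal(integrate_region(sp, reg), A / (2 * sfo), 0.01)
})

test_that("zero FID transforms to a zero spectrum and errors are caught", {
  fid <- make_fid(1000)
  fid$points[] <- 0 + 0i
  sp <- fourier_transform(fid, processing_config(phase_method = "manual"))
  expect_true(all(sp$intensity == 0))
  # zero-fill padding lands on a power of two even for odd lengths
  fid3 <- make_fid(1000, n = 3000)
  sp3 <- fourier_transform(fid3, processing_config(phase_method = "manual"))
  expect_equal(length(sp3$ppm), 8192)  # next pow2 of 6000
})

test_that("known dephasing is recovered within 1 degree", {
  sp <- simulate_control(seed = 1, noise_sd = 0, grid = test_grid)
  sp$imag <- pulcon:::hilbert_imag(sp$intensity)
  rot <- pulcon:::apply_phase(sp$intensity, sp$imag, -30, 0)
  bad <- sp; bad$intensity <- rot$re; bad$imag <- rot$im
  fixed <- phase_correct(bad, processing_config())
  expect_lt(abs(attr(fixed, "ph0") - 30), 1)
  expect_lt(abs(attr(fixed, "ph1")), 1)
  expect_rel_equal(max(fixed$intensity), max(sp$intensity), 0.005)
})

test_that("phasing an already-phased spectrum is a near-identity", {
  sp <- simulate_quantref(seed = 2, noise_sd = 0, grid = test_grid)
  sp$imag <- pulcon:::hilbert_imag(sp$intensity)
  out <- phase_correct(sp, processing_config())
  expect_lt(abs(attr(out, "ph0")), 0.5)
  expect_lt(abs(attr(out, "ph1")), 0.5)
  # area conservation under phase correction
  reg <- integration_region("all", list(c(11.9, -1.9)),
                            ref_compound = "x", ref_mw = 1, n_protons = 1)
  expect_rel_equal(integrate_region(out, reg), integrate_region(sp, reg), 0.01)
})

test_that("pure noise gets zero phase without error", {
  set.seed(3)
  ns <- spectrum1d(seq(12, -2, length.out = 4096), rnorm(4096, 0, 1e-3),
                   spectrometer_freq = 400.13)
  out <- phase_correct(ns, processing_config())
  expect_identical(attr(out, "ph0"), 0)
  expect_identical(attr(out, "ph1"), 0)
})

test_that("baseline correction removes ramps and constants", {
  sp <- simulate_quantref(seed = 4, noise_sd = "calibrated", grid = test_grid)
  sigma <- calibrated_noise_sd()
  ramp <- seq(0.05, -0.02, length.out = length(sp$ppm))
  for (extra in list(ramp, rep(0.37, length(sp$ppm)))) {
    bad <- sp; bad$intensity <- sp$intensity + extra
    fixed <- baseline_correct(bad, processing_config())
    m <- bad$ppm <= 10.5 & bad$ppm > 9.5
    expect_lt(abs(mean(fixed$intensity[m])), 3 * sigma / sqrt(sum(m)) * 10)
  }
})

test_that("baseline correction is a near-identity on flat-baseline spectra", {
  sp <- simulate_quantref(seed = 5, noise_sd = 0, grid = test_grid)
  fixed <- suppressWarnings(baseline_correct(sp, processing_config()))
  regions <- default_regions()
  for (nm in c("quantref_tcnb", "quantref_eb_m", "quantref_eb_q", "quantref_eb_t")) {
    before <- integrate_region(sp, regions[[nm]])
    after <- integrate_region(fixed, regions[[nm]])
    expect_rel_equal(after, before, 0.002)
  }
})

test_that("peak areas above 20x noise survive baseline correction within 1%", {
  sp <- simulate_control(seed = 6, noise_sd = "calibrated", grid = test_grid)
  regions <- default_regions()
  before <- integrate_region(sp, regions$control_cyclohexane)
  after <- integrate_region(baseline_correct(sp, processing_config()),
                            regions$control_cyclohexane)
  expect_rel_equal(after, before, 0.01)
})

test_that("TMS referencing translates the axis onto the reference shift", {
  sp <- simulate_control(seed = 8, noise_sd = 0, grid = test_grid)
  # displace the whole axis by +0.02 ppm: TMS sits at 0.02
  sp$ppm <- sp$ppm + 0.02
  ref <- reference_to_tms(sp, processing_config())
  shift <- ref$ppm[1] - sp$ppm[1]
  expect_equal(shift, -0.02, tolerance = 1e-3)
  # pairwise distances untouched (pure translation)
  expect_equal(diff(ref$ppm), diff(sp$ppm))
  # already-referenced: shift below one grid step
  again <- reference_to_tms(ref, processing_config())
  expect_lt(abs(again$ppm[1] - ref$ppm[1]), abs(diff(ref$ppm[1:2])))
})

test_that("absent TMS flags the spectrum unreferenced and keeps the axis", {
  sp <- simulate_control(seed = 9, noise_sd = "calibrated", grid = test_grid,
                         tms_area = 0)
  expect_warning(out <- reference_to_tms(sp, processing_config()), "unreferenced")
  expect_true(out$flags$unreferenced)
  expect_equal(out$ppm, sp$ppm)
})

test_that("processing is deterministic", {
  fid <- make_fid(2.5 * 400.13, n = 4096)
  cfg <- processing_config()
  a <- process_spectrum(fid, cfg)
  b <- process_spectrum(fid, cfg)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$processing_log, b$processing_log)
})

test_that("alternative baseline methods run and remove a constant offset", {
  sp <- simulate_control(seed = 10, noise_sd = "calibrated",
                         grid = c(-2, 12, 8192))
  sp$intensity <- sp$intensity + 0.02
  # ALS tracks the lower noise envelope (~3 SD below the mean), so the
  # corrected level sits within a few noise SD of zero rather than exactly there
  for (method in c("asymmetric-least-squares", "iterative-polynomial")) {
    out <- suppressWarnings(
      baseline_correct(sp, processing_config(baseline_method = method)))
    m <- sp$ppm <= 10.5 & sp$ppm > 9.5
    expect_lt(abs(mean(out$intensity[m])), 3.5 * calibrated_noise_sd())
  }
})
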