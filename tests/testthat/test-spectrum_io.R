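# JCAMP-DX reading/writing and the core containers.

test_that("container invariants are enforced", {
  expect_error(sample_prep(0, 1.5), "sample_mass")
  expect_error(sample_prep(50, -1), "solution_volume")
  expect_error(fid_record(complex(0), 1e-4, 400), "at least one point")
  expect_error(fid_record(complex(real = 1:4), -1, 400), "dwell_time")
  expect_error(spectrum1d(c(2, 1, 1, 0), rep(0, 4), spectrometer_freq = 400),
               "monotonic")
  expect_error(spectrum1d(c(3, 2, 0.5), rep(0, 3), spectrometer_freq = 400),
               "constant")
  expect_error(spectrum1d(3:1, rep(0, 2), spectrometer_freq = 400),
               "equal length")
  # ascending input is stored descending
  s <- spectrum1d(seq(-1, 1, by = 0.5), 1:5, spectrometer_freq = 400)
  expect_equal(s$ppm, seq(1, -1, by = -0.5))
  expect_equal(s$intensity, 5:1)
})

test_that("ppm axis is reconstructed from the JCAMP header", {
  f <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "##TITLE= minimal", "##JCAMP-DX= 5.01", "##DATA TYPE= NMR SPECTRUM",
    "##.OBSERVE FREQUENCY= 400.13", "##$NS= 1", "##$RG= 1",
    "##XFACTOR= 1", "##YFACTOR= 1",
    "##FIRSTX= 10", "##LASTX= -1", "##NPOINTS= 8",
    "##XYDATA= (X++(Y..Y))",
    "10 1 2 3 4 5 6 7 8",
    "##END="), f)
  s <- read_jcamp(f)
  expect_s3_class(s, "spectrum1d")
  expect_length(s$ppm, 8)
  half_step <- abs(s$ppm[2] - s$ppm[1]) / 2
  expect_lt(abs(s$ppm[1] - 10), half_step)
  expect_lt(abs(s$ppm[8] - (-1)), half_step)
  expect_equal(s$intensity, as.numeric(1:8))
})

test_that("spectrum round trip preserves intensities and metadata", {
  spec <- simulate_control(seed = 7, noise_sd = 1e-3, grid = c(-2, 12, 4096))
  spec$series_id <- "S9"; spec$sample_id <- "ctl"
  f <- withr::local_tempfile(fileext = ".dx")
  write_jcamp(spec, f)
  back <- read_jcamp(f)
  expect_lt(max(abs(back$intensity - spec$intensity)) / max(abs(spec$intensity)),
            1e-6)
  expect_equal(back$ppm, spec$ppm, tolerance = 1e-9)
  expect_identical(back$scans, spec$scans)
  expect_equal(back$receiver_gain, spec$receiver_gain)
  expect_identical(back$series_id, "S9")
  expect_identical(back$sample_id, "ctl")
  expect_equal(back$spectrometer_freq, spec$spectrometer_freq)
})

test_that("FID round trip preserves complex points and dwell time", {
  t <- (0:511) * 2e-4
  fid <- fid_record(complex(real = cos(2 * pi * 500 * t) * exp(-3 * t),
                            imaginary = sin(2 * pi * 500 * t) * exp(-3 * t)),
                    dwell_time = 2e-4, spectrometer_freq = 400.13,
                    scans = 32L, center_ppm = 5, sample_id = "fid1")
  f <- withr::local_tempfile(fileext = ".dx")
  write_jcamp(fid, f)
  back <- read_jcamp(f)
  expect_s3_class(back, "fid_record")
  expect_lt(max(Mod(back$points - fid$points)), 1e-6 * max(Mod(fid$points)))
  expect_equal(back$dwell_time, fid$dwell_time, tolerance = 1e-9)
  expect_equal(back$center_ppm, 5)
  expect_identical(back$scans, 32L)
})

test_that("DIFF/DUP compressed data decodes like its AFFN equivalent", {
  set.seed(42)
  cases <- list(
    c(0, 0, 0, 0, 5, 5, 5, -3, -3, 7),
    round(1000 * sin(seq(0, 4, length.out = 40))),
    rep(123456, 12),
    as.numeric(sample.int(10000, 25) - 5000))
  for (y in cases) {
    line <- asdf_encode_line(0, y)
    dec <- pulcon:::decode_data_line(line)
    expect_equal(dec$values[-1], y)
  }
})

test_that("multi-line DIF blocks honor the y-check value", {
  y1 <- c(10, 12, 15, 15, 15, 20)
  y2 <- c(20, 22, 19)            # first value duplicates last of line 1
  lines <- c(asdf_encode_line(0, y1), asdf_encode_line(5, y2))
  out <- pulcon:::decode_xy_block(lines)
  expect_equal(out, c(y1, y2[-1]))
  # full file with ASDF data equals its AFFN twin
  hdr <- c("##TITLE= t", "##JCAMP-DX= 5.01", "##DATA TYPE= NMR SPECTRUM",
           "##.OBSERVE FREQUENCY= 400", "##$NS= 1", "##$RG= 1",
           "##FIRSTX= 8", "##LASTX= 1", "##NPOINTS= 8",
           "##XYDATA= (X++(Y..Y))")
  f_asdf <- withr::local_tempfile(fileext = ".dx")
  f_affn <- withr::local_tempfile(fileext = ".dx")
  yy <- c(100, 100, 100, 250, 400, 400, 380, 380)
  writeLines(c(hdr, asdf_encode_line(8, yy[1:5]),
               asdf_encode_line(4, yy[5:8]), "##END="), f_asdf)
  writeLines(c(hdr, paste(c(8, yy), collapse = " "), "##END="), f_affn)
  expect_equal(read_jcamp(f_asdf)$intensity, read_jcamp(f_affn)$intensity)
})

test_that("reader fails informatively on malformed input", {
  f <- withr::local_tempfile(fileext = ".dx")
  writeLines(c("##TITLE= x", "##DATA TYPE= NMR SPECTRUM",
               "##FIRSTX= 1", "##LASTX= 0", "##NPOINTS= 2",
               "##XYDATA= (X++(Y..Y))", "1 1 2", "##END="), f)
  expect_error(read_jcamp(f), "frequency")            # missing observe freq
  writeLines(c("##TITLE= x", "##BROKEN LABEL NO EQUALS",
               "##.OBSERVE FREQUENCY= 400"), f)
  expect_error(read_jcamp(f), "missing '='")
  writeLines(c("##TITLE= x", "##DATA TYPE= NMR FID",
               "##.OBSERVE FREQUENCY= 400", "##$NS= 1", "##$RG= 1",
               "##NTUPLES= NMR FID",
               "##PAGE= N=1", "##DATA TABLE= (X++(I..I)), XYDATA",
               "0 1 2 3", "##END="), f)
  expect_error(read_jcamp(f), "imaginary-only")
  expect_error(read_jcamp(tempfile()), "not found")
  # empty spectrum refused on write
  s <- simulate_control(seed = 1, grid = c(-2, 12, 512), noise_sd = 0)
  s$intensity <- numeric(0)
  expect_error(write_jcamp(s, f), "empty")
})

test_that("absent scans/receiver gain default to 1 with a warning", {
  f <- withr::local_tempfile(fileext = ".dx")
  writeLines(c("##TITLE= x", "##DATA TYPE= NMR SPECTRUM",
               "##.OBSERVE FREQUENCY= 400",
               "##FIRSTX= 1", "##LASTX= 0", "##NPOINTS= 3",
               "##XYDATA= (X++(Y..Y))", "1 5 6 7", "##END="), f)
  expect_warning(expect_warning(s <- read_jcamp(f), "scans"), "receiver gain")
  expect_identical(s$scans, 1L)
  expect_equal(s$receiver_gain, 1)
})
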