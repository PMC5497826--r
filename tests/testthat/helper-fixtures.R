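# Shared fixtures. Tests run on a 32768-point grid (same span as the
# default 131072-point grid, 4x coarser) to keep the suite fast; the
# acceptance criteria use the full default grid.

test_grid <- c(-2, 12, 32768)

prep50 <- sample_prep(50, 1.5)

# quantref + eretic, memoized per (seed, noise)
local_eretic <- local({
  cache <- list()
  function(seed = 101, noise_sd = 0) {
    key <- paste(seed, noise_sd)
    if (is.null(cache[[key]])) {
      qr <- simulate_quantref(seed = seed, noise_sd = noise_sd, grid = test_grid)
      cache[[key]] <<- eretic_from_quantref(qr)
    }
    cache[[key]]
  }
})

# a single unit-area Lorentzian spectrum on the test grid
lorentz_spectrum <- function(center, hwhm, area = 1, grid = test_grid,
                             sfo = 400.13) {
  ppm <- seq(grid[2], grid[1], length.out = grid[3])
  y <- area * (hwhm / pi) / ((ppm - center)^2 + hwhm^2)
  spectrum1d(ppm, y, spectrometer_freq = sfo)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
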