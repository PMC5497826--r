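# FID -> referenced, phased, baseline-corrected absorptive spectrum.

#' Processing configuration
#'
#' Parameters controlling conversion of an FID to an absorptive spectrum and
#' the baseline treatment of processed spectra.
#'
#' Baseline methods:
#' \describe{
#'   \item{`masked-whittaker`}{(default) Iteratively flags signal points by
#'     comparing a short running mean of the residual against the noise floor,
#'     then fits a stiff Whittaker (second-difference penalized) smoother
#'     through the remaining baseline points. Signal regions are bridged, so
#'     broad humps several ppm wide are not flattened, and the estimate is
#'     unbiased in pure-noise regions.}
#'   \item{`asymmetric-least-squares`}{Classic asymmetrically weighted
#'     Whittaker smoother (weights `p` above / `1-p` below the baseline).
#'     Tends to sit at the lower noise envelope; kept for comparison.}
#'   \item{`iterative-polynomial`}{Polynomial fit with iterative clipping of
#'     points above the fit.}
#' }
#'
#' @param line_broadening Exponential apodization in Hz (>= 0). Default 0.3,
#'   typical for 400 MHz 1D proton spectra.
#' @param zero_fill_factor Zero-filling multiplier, one of 1, 2, 4. Default 2.
#' @param phase_method `"auto"` (minimize negative intensity) or `"manual"`.
#' @param manual_ph0,manual_ph1 Manual zero/first-order phases in degrees.
#' @param baseline_method One of `"masked-whittaker"`,
#'   `"asymmetric-least-squares"`, `"iterative-polynomial"`.
#' @param baseline_params Named list of method parameters; missing entries are
#'   filled with defaults (`lambda`, `p`, `mask_window_ppm`, `mask_threshold`,
#'   `dilate_ppm`, `iterations`, `degree`).
#' @param reference_shift Target chemical shift of the TMS singlet (ppm).
#' @param noise_region `c(high, low)` ppm window assumed free of analyte
#'   signal, used for all noise-SD estimates. Default `c(10.5, 9.5)`.
#' @return An object of class `processing_config`.
#' @export
processing_config <- function(line_broadening = 0.3,
                              zero_fill_factor = 2,
                              phase_method = c("auto", "manual"),
                              manual_ph0 = 0, manual_ph1 = 0,
                              baseline_method = c("masked-whittaker",
                                                  "asymmetric-least-squares",
                                                  "iterative-polynomial"),
                              baseline_params = list(),
                              reference_shift = 0,
                              noise_region = c(10.5, 9.5)) {
  if (!is.numeric(line_broadening) || line_broadening < 0)
    stop("line_broadening must be >= 0 Hz", call. = FALSE)
  if (!zero_fill_factor %in% c(1, 2, 4))
    stop("zero_fill_factor must be one of 1, 2, 4", call. = FALSE)
  defaults <- list(lambda = 1e12, als_lambda = 1e8, p = 1e-3,
                   mask_window_ppm = 0.1, mask_window_wide_ppm = 0.5,
                   mask_threshold = 4,
                   dilate_ppm = 0.25, iterations = 10, degree = 4,
                   decimate_to = 8192)
  bp <- utils::modifyList(defaults, baseline_params)
  structure(list(line_broadening = line_broadening,
                 zero_fill_factor = zero_fill_factor,
                 phase_method = match.arg(phase_method),
                 manual_ph0 = manual_ph0, manual_ph1 = manual_ph1,
                 baseline_method = match.arg(baseline_method),
                 baseline_params = bp,
                 reference_shift = reference_shift,
                 noise_region = noise_region),
            class = "processing_config")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

#' Fourier transform an FID
#'
#' Applies exponential apodization, halves the first point (suppresses the
#' DC baseline offset), zero-fills to `zero_fill_factor` times the acquired
#' size (padded up to a power of two), Fourier transforms, and scales by the
#' dwell time so that discrete spectral integrals approximate the continuous
#' ones (the area of an exponentially decaying cosine equals its initial
#' amplitude). The result is phase corrected per the configuration and
#' returned with both real and imaginary parts on a descending ppm axis
#' centered at the FID's carrier position.
#'
#' @param fid A [fid_record()].
#' @param cfg A [processing_config()].
#' @return A [spectrum1d()].
#' @export
fourier_transform <- function(fid, cfg = processing_config()) {
  stopifnot(is_fid_record(fid))
  n <- length(fid$points)
  if (n == 0L) stop("zero-length FID", call. = FALSE)
  t <- (seq_len(n) - 1) * fid$dwell_time
  x <- fid$points * exp(-pi * cfg$line_broadening * t)
  x[1] <- x[1] * 0.5
  nfft <- next_pow2(n * cfg$zero_fill_factor)
  x <- c(x, complex(real = rep(0, nfft - n)))
  s <- stats::fft(x) * fid$dwell_time
  f <- (seq_len(nfft) - 1) / (nfft * fid$dwell_time)
  nyq <- 0.5 / fid$dwell_time
  f[f >= nyq] <- f[f >= nyq] - 2 * nyq
  ppm <- fid$center_ppm + f / fid$spectrometer_freq
  ord <- order(ppm, decreasing = TRUE)
  spec <- spectrum1d(ppm[ord], Re(s)[ord], imag = Im(s)[ord],
                     spectrometer_freq = fid$spectrometer_freq,
                     scans = fid$scans, receiver_gain = fid$receiver_gain,
                     series_id = fid$series_id, sample_id = fid$sample_id,
                     processing_log = sprintf(
                       "fourier_transform(lb=%g Hz, zf=%d, n=%d->%d)",
                       cfg$line_broadening, cfg$zero_fill_factor, n, nfft))
  phase_correct(spec, cfg)
}

# Reconstruct the dispersive part of a real absorptive spectrum via the
# discrete Hilbert transform (sign convention irrelevant to the optimizer).
hilbert_imag <- function(y) {
  n <- length(y)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Im(stats::fft(stats::fft(y) * h, inverse = TRUE) / n)
}

apply_phase <- function(re, im, ph0, ph1) {
  n <- length(re)
  frac <- seq(0, 1, length.out = n)
  phi <- (ph0 + ph1 * frac) * pi / 180
  list(re = re * cos(phi) - im * sin(phi),
       im = re * sin(phi) + im * cos(phi))
}

#' Phase correct a spectrum
#'
#' Automatic mode chooses zero- and first-order phases minimizing the summed
#' negative intensity after median-offset removal, a simple objective that is
#' adequate for absorptive spectra with predominantly positive signal. A tiny
#' quadratic regularizer breaks ties toward zero phase for degenerate (e.g.
#' pure-noise) inputs. If the spectrum carries no imaginary part it is
#' reconstructed by Hilbert transform. If the simplex optimizer fails to
#' converge a zero-order-only grid search result is used with a warning.
#'
#' @param spec A [spectrum1d()].
#' @param cfg A [processing_config()]; `phase_method = "manual"` applies
#'   `manual_ph0`/`manual_ph1` directly.
#' @return Phase-corrected [spectrum1d()] (real and imaginary parts rotated);
#'   applied phases are recorded in the processing log and in attributes
#'   `ph0`/`ph1`.
#' @export
phase_correct <- function(spec, cfg = processing_config()) {
  stopifnot(is_spectrum1d(spec))
  re <- spec$intensity
  im <- spec$imag %||% hilbert_imag(re)
  if (cfg$phase_method == "manual") {
    ph <- c(cfg$manual_ph0, cfg$manual_ph1)
  } else if (max(abs(re - stats::median(re))) <
             5 * max(stats::mad(re), 1e-300)) {
    # degenerate input (no signal rising above the noise): any phase pair is
    # as good as any other, so the tie is broken toward zero
    ph <- c(0, 0)
  } else {
    obj <- function(p) {
      r <- apply_phase(re, im, p[1], p[2])$re
      r <- r - stats::median(r)
      sum(pmax(0, -r)) + 1e-9 * (p[1]^2 + p[2]^2)
    }
    grid <- seq(-180, 175, by = 5)
    g0 <- grid[which.min(vapply(grid, function(p0) obj(c(p0, 0)), numeric(1)))]
    fit <- stats::optim(c(g0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (fit$convergence != 0) {
      warning("phase optimizer did not converge; falling back to ph0-only grid search",
              call. = FALSE)
      fine <- seq(g0 - 5, g0 + 5, by = 0.1)
      ph <- c(fine[which.min(vapply(fine, function(p0) obj(c(p0, 0)), numeric(1)))], 0)
    } else ph <- fit$par
  }
  rot <- apply_phase(re, im, ph[1], ph[2])
  spec$intensity <- rot$re
  spec$imag <- rot$im
  spec <- log_op(spec, sprintf("phase_correct(ph0=%.3f, ph1=%.3f)", ph[1], ph[2]))
  attr(spec, "ph0") <- ph[1]
  attr(spec, "ph1") <- ph[2]
  spec
}

# Weighted Whittaker smoother: minimizes sum w (y-z)^2 + lambda sum (d2 z)^2.
# Pentadiagonal sparse system solved with Matrix's Cholesky.
whittaker_smooth <- function(y, w, lambda) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n, x = w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

# Running mean with edge replication.
running_mean <- function(y, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  cs <- cumsum(c(0, y))
  n <- length(y)
  half <- (k - 1L) / 2L
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Dilate a logical mask by m points on each side.
dilate_mask <- function(mask, m) {
  if (m <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  idx <- which(mask)
  out <- logical(n)
  lo <- pmax(1L, idx - m); hi <- pmin(n, idx + m)
  for (i in seq_along(idx)) out[lo[i]:hi[i]] <- TRUE
  out
}

# The baseline is smooth by definition, so it is estimated on a block-mean
# decimated grid (keeps the pentadiagonal system small and well conditioned)
# and interpolated back. Signal points are flagged by comparing a short
# running mean of the residual against the noise floor; masking passes use a
# much stiffer smoother so that broad humps are bridged rather than tracked.
baseline_masked_whittaker <- function(y, step, bp) {
  n <- length(y)
  dec <- max(1L, floor(n / bp$decimate_to))
  nd <- floor(n / dec)
  yd <- if (dec > 1L)
    colMeans(matrix(y[seq_len(nd * dec)], nrow = dec)) else y
  step_d <- step * dec
  w_pts <- max(3L, round(bp$mask_window_ppm / step_d))
  dil <- max(1L, round(bp$dilate_ppm / step_d))
  # robust noise estimate from first differences (insensitive to smooth signal),
  # floored so noise-free input still yields a usable threshold
  sigma0 <- max(stats::mad(diff(yd)) / sqrt(2), 1e-9 * max(abs(yd), 1e-300))
  # wide running median: signal (humps included) occupies less than half of
  # the axis, so the median over half the grid tracks the baseline robustly
  k_med <- min(nd - (1 - nd %% 2), max(3L, nd %/% 2 + (1 - (nd %/% 2) %% 2)))
  ref <- stats::runmed(yd, k_med, endrule = "median")
  mask <- logical(nd)
  bd <- ref
  w_wide <- max(w_pts, round(bp$mask_window_wide_ppm / step_d))
  for (it in 1:3) {
    r <- yd - bd
    # narrow window catches peaks, wide window faint broad humps
    mask <- running_mean(r, w_pts) > bp$mask_threshold * sigma0 / sqrt(w_pts) |
      running_mean(r, w_wide) > bp$mask_threshold * sigma0 / sqrt(w_wide) |
      r > 6 * sigma0
    mask <- dilate_mask(mask, dil)
    if (mean(mask) > 0.95) break   # keep the median reference as baseline
    bd <- whittaker_smooth(yd, as.numeric(!mask), bp$lambda)
  }
  b <- if (dec > 1L) {
    centers <- (seq_len(nd) - 0.5) * dec + 0.5
    stats::approx(centers, bd, xout = seq_len(n), rule = 2)$y
  } else bd
  list(baseline = b, signal_fraction = mean(mask))
}

baseline_als <- function(y, bp) {
  n <- length(y)
  w <- rep(1, n)
  b <- y
  # smaller stiffness than the masked method: the asymmetric weights (~p)
  # would vanish numerically against a 1e12-scale penalty
  for (it in seq_len(bp$iterations)) {
    b <- whittaker_smooth(y, w, bp$als_lambda)
    w <- ifelse(y > b, bp$p, 1 - bp$p)
  }
  list(baseline = b, signal_fraction = mean(y > b))
}

baseline_poly <- function(y, x, bp) {
  keep <- rep(TRUE, length(y))
  b <- rep(0, length(y))
  X <- cbind(1, stats::poly(x, bp$degree, simple = TRUE))
  for (it in seq_len(bp$iterations)) {
    cf <- stats::lm.fit(X[keep, , drop = FALSE], y[keep])$coefficients
    cf[is.na(cf)] <- 0
    b <- drop(X %*% cf)
    resid <- y - b
    s <- stats::sd(resid[keep])
    keep <- resid < 2 * s
    if (!any(keep)) break
  }
  list(baseline = b, signal_fraction = mean(!keep))
}

#' Baseline correct a spectrum
#'
#' Estimates and subtracts a smooth baseline. With the default
#' `masked-whittaker` method, signal-free regions end up with mean intensity
#' within the noise around zero while peaks and broad humps (bridged, not
#' tracked) keep their areas. Always returns a corrected spectrum; a warning
#' is emitted when more than half of all points are classified as signal.
#'
#' @inheritParams phase_correct
#' @return Baseline-corrected [spectrum1d()]; the subtracted baseline is in
#'   attribute `baseline`.
#' @export
baseline_correct <- function(spec, cfg = processing_config()) {
  stopifnot(is_spectrum1d(spec))
  y <- spec$intensity
  bp <- cfg$baseline_params
  res <- switch(cfg$baseline_method,
    "masked-whittaker" = baseline_masked_whittaker(y, ppm_step(spec), bp),
    "asymmetric-least-squares" = baseline_als(y, bp),
    "iterative-polynomial" = baseline_poly(y, seq_along(y), bp))
  if (res$signal_fraction > 0.5)
    warning(sprintf("baseline correction classified %.0f%% of points as signal",
                    100 * res$signal_fraction), call. = FALSE)
  spec$intensity <- y - res$baseline
  spec <- log_op(spec, sprintf("baseline_correct(%s)", cfg$baseline_method))
  attr(spec, "baseline") <- res$baseline
  spec
}

#' Estimate the spectral noise standard deviation
#'
#' Standard deviation of the intensity in a signal-free window, by default
#' delta 10.5-9.5 ppm where none of the quantified regions or standards have
#' signals.
#'
#' @param spec A [spectrum1d()].
#' @param region `c(high, low)` ppm bounds of the noise window.
#' @return Noise SD in intensity units.
#' @export
estimate_noise_sd <- function(spec, region = c(10.5, 9.5)) {
  m <- spec$ppm <= max(region) & spec$ppm > min(region)
  if (!any(m)) stop("noise region outside spectrum axis", call. = FALSE)
  stats::sd(spec$intensity[m])
}

#' Reference the chemical-shift axis to TMS
#'
#' Locates the tallest peak within +/- 0.3 ppm of the expected TMS position
#' and translates the axis so its (parabolically interpolated) maximum sits
#' at `reference_shift` (0.00 ppm by default). Referencing is a pure
#' translation: all peak distances are preserved exactly. If no peak rises
#' at least 3 noise-SD above the local median, the spectrum is returned
#' unchanged with `flags$unreferenced = TRUE` and a warning.
#'
#' @inheritParams phase_correct
#' @param search_halfwidth Half width of the search window in ppm.
#' @return Referenced [spectrum1d()].
#' @export
reference_to_tms <- function(spec, cfg = processing_config(),
                             search_halfwidth = 0.3) {
  stopifnot(is_spectrum1d(spec))
  target <- cfg$reference_shift
  m <- which(spec$ppm <= target + search_halfwidth &
             spec$ppm >= target - search_halfwidth)
  if (!length(m)) stop("TMS search window outside spectrum axis", call. = FALSE)
  y <- spec$intensity[m]
  sigma <- tryCatch(estimate_noise_sd(spec, cfg$noise_region), error = function(e) 0)
  i <- which.max(y)
  if (y[i] - stats::median(y) < 3 * sigma) {
    warning("no TMS peak found in search window; spectrum left unreferenced",
            call. = FALSE)
    spec$flags$unreferenced <- TRUE
    return(log_op(spec, "reference_to_tms(not found)"))
  }
  peak_ppm <- spec$ppm[m[i]]
  if (i > 1 && i < length(y)) {   # parabolic apex interpolation
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    if (denom < 0) {
      delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
      peak_ppm <- peak_ppm + delta * (spec$ppm[m[i] + 1] - spec$ppm[m[i]])
    }
  }
  shift <- target - peak_ppm
  spec$ppm <- spec$ppm + shift
  spec$flags$unreferenced <- FALSE
  log_op(spec, sprintf("reference_to_tms(shift=%+.5f ppm)", shift))
}

#' Standard processing chain for an input spectrum or FID
#'
#' FIDs are Fourier transformed (including phasing); spectra and transformed
#' FIDs are then baseline corrected and referenced to TMS.
#'
#' @param x A [fid_record()] or [spectrum1d()].
#' @param cfg A [processing_config()].
#' @param reference Logical, run TMS referencing (default TRUE).
#' @return A processed [spectrum1d()].
#' @export
process_spectrum <- function(x, cfg = processing_config(), reference = TRUE) {
  if (is_fid_record(x)) x <- fourier_transform(x, cfg)
  stopifnot(is_spectrum1d(x))
  x <- baseline_correct(x, cfg)
  if (reference) x <- reference_to_tms(x, cfg)
  x
}
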