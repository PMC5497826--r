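# Core containers: 1D spectra, FIDs and sample-preparation metadata.

#' Sample preparation metadata
#'
#' Records how a sample was dissolved for measurement. Mass fraction
#' conversion (g/L to g/100 g) needs the weighed sample mass and the
#' solution volume; the tube volume actually transferred is informational
#' only and does not enter any calculation.
#'
#' @param sample_mass Weighed sample mass in mg (must be > 0).
#' @param solution_volume Solution volume in mL (must be > 0).
#' @param tube_volume_used Volume transferred to the NMR tube in mL
#'   (informational, default `NA`).
#' @return An object of class `sample_prep`.
#' @examples
#' sample_prep(50, 1.5)
#' @export
sample_prep <- function(sample_mass, solution_volume, tube_volume_used = NA_real_) {
  stopifnot(is.numeric(sample_mass), length(sample_mass) == 1L,
            is.numeric(solution_volume), length(solution_volume) == 1L)
  if (!is.finite(sample_mass) || sample_mass <= 0)
    stop("sample_mass must be a positive number of mg", call. = FALSE)
  if (!is.finite(solution_volume) || solution_volume <= 0)
    stop("solution_volume must be a positive number of mL", call. = FALSE)
  structure(list(sample_mass = as.numeric(sample_mass),
                 solution_volume = as.numeric(solution_volume),
                 tube_volume_used = as.numeric(tube_volume_used)),
            class = "sample_prep")
}

#' Time-domain free induction decay record
#'
#' Container for a complex 1D FID together with the acquisition metadata
#' required downstream: the dwell time fixes the spectral width, the
#' spectrometer frequency converts Hz to ppm, and scans/receiver gain are
#' carried so that spectra acquired under non-constant conditions can be
#' normalized before external calibration (off by default, since PULCON
#' comparability assumes constant acquisition parameters).
#'
#' @param points Complex vector of time-domain intensities.
#' @param dwell_time Seconds per point (> 0).
#' @param spectrometer_freq Proton observe frequency in MHz (> 0).
#' @param scans Number of scans (default 1).
#' @param receiver_gain Receiver gain, unitless (default 1).
#' @param center_ppm Chemical shift of the carrier (ppm, default 0); the
#'   transformed axis is centered here.
#' @param series_id,sample_id Identifiers carried through the pipeline.
#' @return An object of class `fid_record`.
#' @export
fid_record <- function(points, dwell_time, spectrometer_freq,
                       scans = 1L, receiver_gain = 1, center_ppm = 0,
                       series_id = NA_character_, sample_id = NA_character_) {
  if (length(points) == 0L) stop("FID must contain at least one point", call. = FALSE)
  if (!is.complex(points)) points <- as.complex(points)
  if (!is.finite(dwell_time) || dwell_time <= 0)
    stop("dwell_time must be > 0 seconds", call. = FALSE)
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0)
    stop("spectrometer_freq must be > 0 MHz", call. = FALSE)
  structure(list(points = points,
                 dwell_time = as.numeric(dwell_time),
                 spectrometer_freq = as.numeric(spectrometer_freq),
                 scans = as.integer(scans),
                 receiver_gain = as.numeric(receiver_gain),
                 center_ppm = as.numeric(center_ppm),
                 series_id = series_id,
                 sample_id = sample_id),
            class = "fid_record")
}

#' Frequency-domain 1D spectrum
#'
#' The object every pipeline stage consumes or produces: a real absorptive
#' intensity vector on a strictly monotonic, evenly spaced chemical-shift
#' axis stored in descending order (NMR display convention). An optional
#' imaginary part is kept when available so that phase correction can act on
#' the complex signal; it is dropped on JCAMP-DX export.
#'
#' @param ppm Chemical-shift axis in ppm, strictly monotonic with constant
#'   spacing (relative tolerance 1e-9). Ascending input is reversed.
#' @param intensity Real intensities (arbitrary units), same length as `ppm`.
#' @param imag Optional imaginary (dispersive) part, same length.
#' @param spectrometer_freq Observe frequency in MHz.
#' @param scans,receiver_gain Acquisition metadata (default 1 each).
#' @param prep Optional [sample_prep()] metadata.
#' @param series_id,sample_id Identifiers.
#' @param processing_log Character vector of applied operations.
#' @param flags Named list of warning flags (e.g. `unreferenced`).
#' @return An object of class `spectrum1d`.
#' @export
spectrum1d <- function(ppm, intensity, imag = NULL, spectrometer_freq,
                       scans = 1L, receiver_gain = 1, prep = NULL,
                       series_id = NA_character_, sample_id = NA_character_,
                       processing_log = character(), flags = list()) {
  n <- length(ppm)
  if (n < 2L) stop("spectrum needs at least two points", call. = FALSE)
  if (length(intensity) != n)
    stop("ppm axis and intensity must have equal length", call. = FALSE)
  if (!is.null(imag) && length(imag) != n)
    stop("imaginary part must match axis length", call. = FALSE)
  d <- diff(ppm)
  if (any(d == 0) || !(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotonic", call. = FALSE)
  rng <- range(abs(d))
  if ((rng[2] - rng[1]) > 1e-9 * rng[2])
    stop("ppm axis spacing must be constant (relative tolerance 1e-9)", call. = FALSE)
  if (d[1] > 0) {            # store descending
    ppm <- rev(ppm); intensity <- rev(intensity)
    if (!is.null(imag)) imag <- rev(imag)
  }
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0)
    stop("spectrometer_freq must be > 0 MHz", call. = FALSE)
  structure(list(ppm = as.numeric(ppm),
                 intensity = as.numeric(intensity),
                 imag = if (is.null(imag)) NULL else as.numeric(imag),
                 spectrometer_freq = as.numeric(spectrometer_freq),
                 scans = as.integer(scans),
                 receiver_gain = as.numeric(receiver_gain),
                 prep = prep,
                 series_id = series_id,
                 sample_id = sample_id,
                 processing_log = processing_log,
                 flags = flags),
            class = "spectrum1d")
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, %.4f to %.4f ppm @ %.2f MHz\n",
              length(x$ppm), x$ppm[1], x$ppm[length(x$ppm)], x$spectrometer_freq))
  if (!is.na(x$sample_id)) cat("  sample:", x$sample_id, "\n")
  if (length(x$processing_log))
    cat("  processing:", paste(x$processing_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.fid_record <- function(x, ...) {
  cat(sprintf("<fid_record> %d complex points, dwell %.3g s, %.2f MHz, %d scans\n",
              length(x$points), x$dwell_time, x$spectrometer_freq, x$scans))
  invisible(x)
}

#' @rdname spectrum1d
#' @param x Object to test.
#' @export
is_spectrum1d <- function(x) inherits(x, "spectrum1d")

#' @rdname fid_record
#' @param x Object to test.
#' @export
is_fid_record <- function(x) inherits(x, "fid_record")

# Absolute grid step in ppm.
ppm_step <- function(spec) abs(spec$ppm[2] - spec$ppm[1])

# Append an entry to the processing log.
log_op <- function(spec, entry) {
  spec$processing_log <- c(spec$processing_log, entry)
  spec
}
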