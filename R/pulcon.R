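# PULCON/ERETIC quantification core: region integration, calibration factor,
# concentrations, mass fractions, PAH4 targets and detection limits.
#
# Calibration:    ERETIC = I * MW / (C * N)   (per quantref signal, averaged)
# Quantification: C      = I * MW / (ERETIC * N)
# where I is the absolute integral, MW the molecular weight of the reference
# compound, N its proton count and C the concentration in g/L.

#' Integrate a spectral region
#'
#' Riemann sum (intensity times ppm step) over the region's included grid
#' points, exclusions removed. The sum is additive over disjoint sub-windows
#' and the same convention is used for the quantification reference and the
#' samples, so the arbitrary intensity scale cancels in PULCON.
#'
#' Integrals can optionally be normalized by scans x receiver gain, for
#' series where acquisition parameters were not constant; this is off by
#' default because external calibration assumes constant acquisition.
#'
#' @param spec A referenced, baseline-corrected [spectrum1d()].
#' @param region An [integration_region()].
#' @param normalize_by_ns_rg Divide by `scans * receiver_gain` (default FALSE).
#' @return Absolute integral (intensity x ppm units).
#' @export
integrate_region <- function(spec, region, normalize_by_ns_rg = FALSE) {
  stopifnot(is_spectrum1d(spec), inherits(region, "integration_region"))
  axis_hi <- max(spec$ppm); axis_lo <- min(spec$ppm)
  for (w in region$windows)
    if (w[1] > axis_hi || w[2] < axis_lo)
      stop(sprintf("region '%s' window [%g, %g] outside spectrum axis [%g, %g]",
                   region$name, w[1], w[2], axis_lo, axis_hi), call. = FALSE)
  m <- region_mask(spec, region)
  if (!any(m)) {
    warning(sprintf("region '%s' contains no grid points (fully excluded)",
                    region$name), call. = FALSE)
    return(0)
  }
  val <- sum(spec$intensity[m]) * ppm_step(spec)
  if (normalize_by_ns_rg) val <- val / (spec$scans * spec$receiver_gain)
  val
}

#' Quantification reference recipe
#'
#' Concentrations of the two calibration compounds in the quantref sample.
#' The default corresponds to 50 mg of tetrachloronitrobenzene and 50 mg of
#' ethylbenzene dissolved in 10 mL of CDCl3: 5.0 g/L each.
#'
#' @param tcnb_conc Tetrachloronitrobenzene concentration (g/L).
#' @param eb_conc Ethylbenzene concentration (g/L).
#' @return An object of class `quantref_recipe`.
#' @export
quantref_recipe <- function(tcnb_conc = 5.0, eb_conc = 5.0) {
  stopifnot(tcnb_conc > 0, eb_conc > 0)
  structure(list(tcnb_conc = tcnb_conc, eb_conc = eb_conc),
            class = "quantref_recipe")
}

#' ERETIC calibration factor from a quantref spectrum
#'
#' Integrates the four reference signals (the tetrachloronitrobenzene singlet
#' at 7.83-7.64 ppm, N=1, and the ethylbenzene multiplet 7.23-7.11 N=3,
#' quartet 2.75-2.54 N=2 and triplet 1.35-1.13 N=3) and computes a per-signal
#' factor `I * MW / (C * N)`. The series factor is the arithmetic mean of the
#' four. When the per-signal spread (max/min - 1) exceeds `spread_tol` the
#' factor is flagged invalid and downstream quantification refuses to use it.
#'
#' @param spec Processed quantref [spectrum1d()].
#' @param recipe A [quantref_recipe()].
#' @param regions Region scheme from [default_regions()].
#' @param spread_tol Maximum tolerated per-signal relative spread (default 0.10).
#' @param normalize_by_ns_rg Passed to [integrate_region()].
#' @return An object of class `eretic_factor` with elements `value`,
#'   `per_signal` (named length-4), `spread`, `series_id`, `valid`.
#' @export
eretic_from_quantref <- function(spec, recipe = quantref_recipe(),
                                 regions = default_regions(),
                                 spread_tol = 0.10,
                                 normalize_by_ns_rg = FALSE) {
  sig_names <- c("quantref_tcnb", "quantref_eb_m", "quantref_eb_q", "quantref_eb_t")
  concs <- c(recipe$tcnb_conc, recipe$eb_conc, recipe$eb_conc, recipe$eb_conc)
  per <- vapply(seq_along(sig_names), function(i) {
    reg <- regions[[sig_names[i]]]
    I <- integrate_region(spec, reg, normalize_by_ns_rg)
    if (I <= 0)
      stop("calibration error: non-positive integral for signal ", sig_names[i],
           call. = FALSE)
    I * reg$ref_mw / (concs[i] * reg$n_protons)
  }, numeric(1))
  names(per) <- sig_names
  spread <- max(per) / min(per) - 1
  valid <- spread <= spread_tol
  if (!valid)
    warning(sprintf("ERETIC per-signal spread %.1f%% exceeds %.0f%%; factor flagged invalid",
                    100 * spread, 100 * spread_tol), call. = FALSE)
  structure(list(value = mean(per), per_signal = per, spread = spread,
                 series_id = spec$series_id, valid = valid),
            class = "eretic_factor")
}

#' @export
print.eretic_factor <- function(x, ...) {
  cat(sprintf("<eretic_factor> %.6g (spread %.2f%%, %s)\n", x$value,
              100 * x$spread, if (x$valid) "valid" else "INVALID"))
  invisible(x)
}

#' Quantify a region against an ERETIC factor
#'
#' Converts the absolute integral of a region to a concentration in g/L via
#' `C = I * MW / (ERETIC * N)`. Negative integrals (possible in blank windows
#' containing only noise) are clamped to a concentration of zero; the raw
#' value is retained in `raw_concentration`.
#'
#' @param spec Processed [spectrum1d()].
#' @param region An [integration_region()].
#' @param eretic An [eretic_from_quantref()] factor. An invalid factor causes
#'   an error unless `force = TRUE` (mirrors the series QC gate).
#' @param force Quantify despite an invalid calibration factor.
#' @param normalize_by_ns_rg Passed to [integrate_region()].
#' @return A `quant_result`: analyte, absolute integral, concentration (g/L),
#'   mass fraction (g/100 g, `NA` until [to_mass_fraction()]), LOD and
#'   detectability flag (`NA` until set by the PAH4/LOD machinery).
#' @export
quantify <- function(spec, region, eretic, force = FALSE,
                     normalize_by_ns_rg = FALSE) {
  stopifnot(inherits(eretic, "eretic_factor"))
  if (!isTRUE(eretic$valid) && !force)
    stop("refusing to quantify with an invalid ERETIC factor (use force = TRUE to override)",
         call. = FALSE)
  I <- integrate_region(spec, region, normalize_by_ns_rg)
  C <- I * region$ref_mw / (eretic$value * region$n_protons)
  structure(list(analyte = region$name,
                 absolute_integral = I,
                 concentration = max(0, C),
                 raw_concentration = C,
                 mass_fraction = NA_real_,
                 lod_mass_fraction = NA_real_,
                 detected = NA),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %s: C = %.4g g/L", x$analyte, x$concentration))
  if (!is.na(x$mass_fraction))
    cat(sprintf(", %s g/100 g", format_mass_fraction(x)))
  cat("\n")
  invisible(x)
}

#' Convert a concentration to a mass fraction
#'
#' `mass_fraction [g/100 g] = C [g/L] * solution_volume [mL] / sample_mass [mg] * 100`
#' (a fully dissolved pure sample at 50 mg in 1.5 mL, i.e. 33.33 g/L, reads
#' 100 g/100 g).
#'
#' @param result A `quant_result` from [quantify()].
#' @param prep A [sample_prep()]; if `NULL`/missing the result is flagged
#'   unconvertible (`mass_fraction` stays `NA`).
#' @return The updated `quant_result`.
#' @export
to_mass_fraction <- function(result, prep) {
  stopifnot(inherits(result, "quant_result"))
  if (missing(prep) || is.null(prep)) {
    result$unconvertible <- TRUE
    warning("missing sample preparation metadata; mass fraction not computed",
            call. = FALSE)
    return(result)
  }
  stopifnot(inherits(prep, "sample_prep"))
  result$mass_fraction <-
    result$concentration * prep$solution_volume / prep$sample_mass * 100
  result
}

#' Estimate the limit of detection for a region
#'
#' Automates the "smallest still-integratable signal" judgment: the LOD is
#' the mass fraction of a synthetic Lorentzian reference peak (half width at
#' half maximum `ref_hwhm`, the narrowest multiplet width simulated for the
#' targeted analytes) whose height equals 3x the spectral noise SD. A
#' Lorentzian of height h and HWHM g has area `pi * h * g`, so
#' `I_LOD = 3 * sigma * pi * ref_hwhm` which is converted to g/L and then to
#' g/100 g with the sample preparation; the LOD therefore scales inversely
#' with sample mass.
#'
#' @param spec Processed [spectrum1d()].
#' @param region Target [integration_region()].
#' @param eretic An `eretic_factor`.
#' @param prep A [sample_prep()].
#' @param noise_region `c(high, low)` ppm noise window.
#' @param ref_hwhm Reference peak half width at half maximum in ppm
#'   (default 0.002).
#' @return LOD in g/100 g (0 with a warning for noise-free spectra).
#' @export
estimate_lod <- function(spec, region, eretic, prep,
                         noise_region = c(10.5, 9.5), ref_hwhm = 0.002) {
  sigma <- estimate_noise_sd(spec, noise_region)
  if (sigma == 0) {
    warning("zero noise estimate; LOD reported as 0", call. = FALSE)
    return(0)
  }
  I_lod <- 3 * sigma * pi * ref_hwhm
  C_lod <- I_lod * region$ref_mw / (eretic$value * region$n_protons)
  C_lod * prep$solution_volume / prep$sample_mass * 100
}

#' Targeted PAH4 quantification
#'
#' Quantifies the four EFSA marker PAHs in their windows (benz[a]anthracene
#' 9.20-9.12 ppm N=1, benzo[a]pyrene 9.06-8.98 N=2, chrysene 8.76-8.70 N=2,
#' benzo[b]fluoranthene 7.45-7.38 N=2). An analyte counts as detected when
#' the maximum intensity in its window reaches 3x the noise SD (boundary
#' inclusive); otherwise the result is reported as "n.d. < LOD" with the LOD
#' from [estimate_lod()].
#'
#' @inheritParams estimate_lod
#' @inheritParams quantify
#' @param regions Region scheme from [default_regions()].
#' @return Named list of four `quant_result`s.
#' @export
quantify_pah4 <- function(spec, eretic, prep, regions = default_regions(),
                          noise_region = c(10.5, 9.5), ref_hwhm = 0.002,
                          force = FALSE, normalize_by_ns_rg = FALSE) {
  pah <- Filter(function(r) r$role == "pah4", regions)
  sigma <- estimate_noise_sd(spec, noise_region)
  out <- lapply(pah, function(reg) {
    res <- quantify(spec, reg, eretic, force = force,
                    normalize_by_ns_rg = normalize_by_ns_rg)
    res <- to_mass_fraction(res, prep)
    res$lod_mass_fraction <- estimate_lod(spec, reg, eretic, prep,
                                          noise_region, ref_hwhm)
    peak_height <- max(spec$intensity[region_mask(spec, reg)])
    res$detected <- peak_height >= 3 * sigma   # inclusive at the boundary
    if (!res$detected) res$mass_fraction <- NA_real_
    res
  })
  names(out) <- names(pah)
  out
}

#' Format a mass fraction Table-style
#'
#' Detected results print as the mass fraction rounded to 2 decimals;
#' non-detects print as `"n.d. <LOD"` with the LOD rounded to 2 decimals.
#'
#' @param result A `quant_result`.
#' @param digits Decimal places (default 2).
#' @return Character scalar.
#' @export
format_mass_fraction <- function(result, digits = 2) {
  if (isTRUE(result$detected) || (is.na(result$detected) && !is.na(result$mass_fraction)))
    sprintf(paste0("%.", digits, "f"), result$mass_fraction)
  else if (!is.na(result$lod_mass_fraction))
    sprintf(paste0("n.d. <%.", digits, "f"), result$lod_mass_fraction)
  else "n.d."
}
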