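# Series quality control and method-validation statistics.

#' Control-sample recovery check
#'
#' The control solution (cyclohexane at 2500 mg/L in CDCl3, singlet at
#' 1.53-1.36 ppm, N = 12) is measured at the end of each series to check the
#' ERETIC factor. The recovery must fall inside the closed interval
#' [95, 105] % ("100 +/- 5 %", read inclusively) for the series to be valid;
#' otherwise downstream quantification should be blocked.
#'
#' @param spec Processed control [spectrum1d()].
#' @param eretic An `eretic_factor` from [eretic_from_quantref()].
#' @param regions Region scheme from [default_regions()].
#' @param nominal_conc Nominal control concentration in mg/L (default 2500).
#' @param force,normalize_by_ns_rg Passed to [quantify()].
#' @return An object of class `control_check`: `nominal_conc`,
#'   `measured_conc` (mg/L), `recovery` (%), `passed`.
#' @export
control_recovery <- function(spec, eretic, regions = default_regions(),
                             nominal_conc = 2500, force = FALSE,
                             normalize_by_ns_rg = FALSE) {
  res <- quantify(spec, regions$control_cyclohexane, eretic, force = force,
                  normalize_by_ns_rg = normalize_by_ns_rg)
  measured <- res$concentration * 1000   # g/L -> mg/L
  recovery <- measured / nominal_conc * 100
  # closed interval, with a relative epsilon so a recovery of exactly 95 or
  # 105 passes regardless of floating-point rounding in the integration
  eps <- 1e-9
  structure(list(nominal_conc = nominal_conc, measured_conc = measured,
                 recovery = recovery,
                 passed = recovery >= 95 * (1 - eps) && recovery <= 105 * (1 + eps)),
            class = "control_check")
}

#' @export
print.control_check <- function(x, ...) {
  cat(sprintf("<control_check> %.1f mg/L measured vs %.0f nominal: recovery %.1f%% [%s]\n",
              x$measured_conc, x$nominal_conc, x$recovery,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, in percent. Scale-invariant:
#' `cv(k * x) == cv(x)` for any k > 0.
#'
#' @param values Numeric vector of replicate measurements (length >= 2,
#'   non-zero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 replicates", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined", call. = FALSE)
  stats::sd(values) / m * 100
}

#' Spike recovery of a validation series
#'
#' Per-level recovery percentages of measured versus spiked amounts,
#' together with their mean and coefficient of variation. Recoveries are
#' computed from the unrounded values supplied.
#'
#' @param spiked Numeric vector of spiked amounts (> 0), or a data frame
#'   with columns `spiked` and `measured`.
#' @param measured Numeric vector of measured amounts (same length).
#' @return A `validation_series` list: `spiked`, `measured`, `recoveries`
#'   (%), `mean_recovery`, `cv` (CV of the recoveries; `NA` for a single
#'   level).
#' @export
spike_recovery <- function(spiked, measured) {
  if (is.data.frame(spiked)) {
    measured <- spiked$measured
    spiked <- spiked$spiked
  }
  stopifnot(length(spiked) == length(measured))
  if (any(spiked <= 0)) stop("spiked amounts must be > 0", call. = FALSE)
  rec <- measured / spiked * 100
  structure(list(spiked = spiked, measured = measured, recoveries = rec,
                 mean_recovery = mean(rec),
                 cv = if (length(rec) >= 2) coefficient_of_variation(rec)
                      else NA_real_),
            class = "validation_series")
}

#' @export
print.validation_series <- function(x, ...) {
  cat("<validation_series>\n")
  print(data.frame(spiked = x$spiked, measured = x$measured,
                   recovery = sprintf("%.1f%%", x$recoveries)))
  cat(sprintf("mean recovery %.1f%%", x$mean_recovery))
  if (!is.na(x$cv)) cat(sprintf(", CV %.1f%%", x$cv))
  cat("\n")
  invisible(x)
}
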