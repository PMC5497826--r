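# Named ppm integration windows with exclusion sub-windows, each bound to a
# reference compound used to express the integral as an equivalent
# concentration.

.region_roles <- c("mosh", "moah", "other", "pah4", "quantref_signal", "control")

#' Integration region
#'
#' A named set of ppm windows (with optional exclusion sub-windows) bound to
#' a reference compound. Window bounds are `(high, low)` pairs on the
#' descending ppm axis. Grid points are assigned to a window by the
#' half-open convention `low < ppm <= high`, so adjacent regions sharing a
#' bound (e.g. the "other compounds" region ending at 3.00 ppm where the
#' saturates region begins) never double-count a point.
#'
#' @param name Region name.
#' @param windows List of `c(high, low)` included intervals.
#' @param exclusions List of `c(high, low)` sub-intervals removed; each must
#'   lie inside the union of the windows.
#' @param ref_compound Reference compound name.
#' @param ref_mw Molecular weight of the reference compound (g/mol).
#' @param n_protons Proton count N of the reference signal (>= 1).
#' @param role One of `"mosh"`, `"moah"`, `"other"`, `"pah4"`,
#'   `"quantref_signal"`, `"control"`.
#' @return An object of class `integration_region`.
#' @export
integration_region <- function(name, windows, exclusions = list(),
                               ref_compound, ref_mw, n_protons,
                               role = "mosh") {
  if (!is.list(windows)) windows <- list(windows)
  if (!is.list(exclusions)) exclusions <- list(exclusions)
  for (w in windows)
    if (length(w) != 2 || w[1] <= w[2])
      stop("each window must be c(high, low) with high > low", call. = FALSE)
  inside <- function(e) any(vapply(windows, function(w)
    e[1] <= w[1] && e[2] >= w[2], logical(1)))
  for (e in exclusions) {
    if (length(e) != 2 || e[1] <= e[2])
      stop("each exclusion must be c(high, low) with high > low", call. = FALSE)
    if (!inside(e))
      stop("exclusion [", e[1], ", ", e[2], "] lies outside the region windows",
           call. = FALSE)
  }
  if (!is.numeric(ref_mw) || ref_mw <= 0) stop("ref_mw must be > 0", call. = FALSE)
  if (!is.numeric(n_protons) || n_protons < 1)
    stop("n_protons must be >= 1", call. = FALSE)
  role <- match.arg(role, .region_roles)
  structure(list(name = name, windows = windows, exclusions = exclusions,
                 ref_compound = ref_compound, ref_mw = as.numeric(ref_mw),
                 n_protons = as.numeric(n_protons), role = role),
            class = "integration_region")
}

#' @export
print.integration_region <- function(x, ...) {
  win <- paste(vapply(x$windows, function(w) sprintf("%.2f-%.2f", w[1], w[2]),
                      character(1)), collapse = ", ")
  cat(sprintf("<integration_region> %s [%s]: %s ppm (%s, MW %.2f, N=%g)\n",
              x$name, x$role, win, x$ref_compound, x$ref_mw, x$n_protons))
  invisible(x)
}

# environment cache for the shipped scheme
.regions_cache <- new.env(parent = emptyenv())

#' Default integration region scheme
#'
#' The shipped, versioned window scheme: saturates (MOSH, decalin
#' equivalents, delta 3.0-0.2 ppm minus the residual-water window), aromatics
#' (MOAH, naphthalene equivalents, delta 9.2-6.5 ppm in four sub-windows that
#' cut out residual CHCl3 and its 13C satellites), "other compounds"
#' (glycerol equivalents, delta 6.5-3.0), the four PAH4 target windows, the
#' four quantification-reference signals and the cyclohexane control window.
#' Loaded from `inst/extdata/regions.yaml`.
#'
#' @param water_exclusion `c(high, low)` ppm exclusion applied inside the
#'   MOSH window for residual water (default `c(1.58, 1.50)`); the control
#'   window never carries it.
#' @param file Alternative scheme YAML.
#' @return Named list of [integration_region()] objects, with the scheme
#'   version in attribute `version`.
#' @export
default_regions <- function(water_exclusion = c(1.58, 1.50), file = NULL) {
  key <- paste0(water_exclusion, collapse = "_")
  if (is.null(file) && !is.null(.regions_cache[[key]]))
    return(.regions_cache[[key]])
  path <- file %||% system.file("extdata", "regions.yaml", package = "pulcon",
                                mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  regs <- lapply(names(raw$regions), function(nm) {
    r <- raw$regions[[nm]]
    excl <- lapply(r$exclusions, as.numeric)
    if (nm == "mosh") excl <- list(as.numeric(water_exclusion))
    integration_region(nm, lapply(r$windows, as.numeric), excl,
                       r$ref_compound, r$ref_mw, r$n_protons, r$role)
  })
  names(regs) <- names(raw$regions)
  attr(regs, "version") <- raw$version
  if (is.null(file)) .regions_cache[[key]] <- regs
  regs
}

#' Grid-point mask of an integration region
#'
#' Logical vector marking the spectrum points belonging to the region:
#' inside any window (`low < ppm <= high`) and inside no exclusion.
#'
#' @param spec A [spectrum1d()].
#' @param region An [integration_region()].
#' @return Logical vector along the spectrum axis.
#' @export
region_mask <- function(spec, region) {
  ppm <- spec$ppm
  m <- rep(FALSE, length(ppm))
  for (w in region$windows) m <- m | (ppm > w[2] & ppm <= w[1])
  for (e in region$exclusions) m <- m & !(ppm > e[2] & ppm <= e[1])
  m
}

# Total included width (ppm) of a region, exclusions subtracted.
region_width <- function(region) {
  w <- sum(vapply(region$windows, function(x) x[1] - x[2], numeric(1)))
  w - sum(vapply(region$exclusions, function(x) x[1] - x[2], numeric(1)))
}
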