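# Series-level orchestration: quantref -> samples -> control, with QC gating
# and report generation (JSON is the source of truth; CSV and text mirror it).

#' Default pipeline configuration
#'
#' @return Nested list of configuration defaults (see [validate_config()]).
#' @export
default_config <- function() {
  list(
    processing = list(line_broadening = 0.3, zero_fill_factor = 2,
                      phase_method = "auto",
                      baseline_method = "masked-whittaker",
                      reference_shift = 0.0, noise_region = c(10.5, 9.5)),
    quantref = list(tcnb_conc = 5.0, eb_conc = 5.0, spread_tol = 0.10),
    control = list(nominal_conc = 2500),
    detection = list(ref_hwhm = 0.002),
    regions = list(water_exclusion = c(1.58, 1.50))
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, warns about (and drops) unknown keys, builds the region
#' scheme and checks its geometry: window bounds ordered, exclusions inside
#' their windows, and every PAH4 window contained in one of the aromatic
#' (MOAH) sub-windows, as the scheme requires. The normalized configuration
#' is echoed into reports for provenance.
#'
#' @param config Nested list (e.g. from `yaml::read_yaml()`), or a path to a
#'   YAML file, or `NULL` for pure defaults.
#' @return A `pulcon_config`: the normalized list plus `$processing_config`
#'   ([processing_config()]) and `$region_scheme` ([default_regions()]).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config %||% list()
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    config <- config[setdiff(names(config), unknown)]
  }
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      warning("ignoring unknown config keys in '", sec, "': ",
              paste(bad, collapse = ", "), call. = FALSE)
      config[[sec]] <- config[[sec]][setdiff(names(config[[sec]]), bad)]
    }
  }
  cfg <- utils::modifyList(defaults, config)
  pc <- processing_config(
    line_broadening = cfg$processing$line_broadening,
    zero_fill_factor = cfg$processing$zero_fill_factor,
    phase_method = cfg$processing$phase_method,
    baseline_method = cfg$processing$baseline_method,
    reference_shift = cfg$processing$reference_shift,
    noise_region = as.numeric(cfg$processing$noise_region))
  regions <- default_regions(as.numeric(cfg$regions$water_exclusion))
  # geometry checks beyond the constructors: PAH4 windows inside the
  # aromatic sub-windows
  moah_wins <- regions$moah$windows
  offenders <- character()
  for (r in regions) {
    if (r$role != "pah4") next
    w <- r$windows[[1]]
    ok <- any(vapply(moah_wins, function(mw) w[1] <= mw[1] && w[2] >= mw[2],
                     logical(1)))
    if (!ok) offenders <- c(offenders, r$name)
  }
  if (length(offenders))
    stop("config error: PAH4 window(s) outside the aromatic sub-windows: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  cfg$processing_config <- pc
  cfg$region_scheme <- regions
  class(cfg) <- "pulcon_config"
  cfg
}

#' Series manifest
#'
#' Describes one measurement series: the quantification reference measured
#' first, the samples, and the control solution measured last.
#'
#' @param series_id Series identifier.
#' @param quantref_path Path to the quantref JCAMP-DX file.
#' @param samples Data frame with columns `path`, `sample_id`, `sample_mass`
#'   (mg), `solution_volume` (mL) and optionally `category`.
#' @param control_path Path to the control JCAMP-DX file (`NA` allowed only
#'   when [run_series()] is called with `allow_missing_control = TRUE`).
#' @return An object of class `series_manifest`.
#' @export
series_manifest <- function(series_id, quantref_path, samples,
                            control_path = NA_character_) {
  stopifnot(is.data.frame(samples),
            all(c("path", "sample_id") %in% names(samples)))
  if (!"category" %in% names(samples)) samples$category <- NA_character_
  if (!"sample_mass" %in% names(samples)) samples$sample_mass <- NA_real_
  if (!"solution_volume" %in% names(samples)) samples$solution_volume <- NA_real_
  structure(list(series_id = series_id, quantref_path = quantref_path,
                 samples = samples, control_path = control_path),
            class = "series_manifest")
}

#' Read a series manifest from YAML
#'
#' @param path YAML file with keys `series_id`, `quantref`, `control` and a
#'   `samples` list of `path`/`sample_id`/`sample_mass`/`solution_volume`/
#'   `category` entries.
#' @return A [series_manifest()].
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(m$samples, function(s)
    data.frame(path = s$path, sample_id = s$sample_id,
               sample_mass = s$sample_mass %||% NA_real_,
               solution_volume = s$solution_volume %||% NA_real_,
               category = s$category %||% NA_character_)))
  # relative paths resolve against the manifest location
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(!is.na(p) & !grepl("^/", p), file.path(base, p), p)
  series_manifest(m$series_id %||% "series", fix(m$quantref),
                  transform(samples, path = fix(path)),
                  if (is.null(m$control)) NA_character_ else fix(m$control))
}

quantify_sample <- function(spec, eretic, prep, cfg, normalize_by_ns_rg) {
  regions <- cfg$region_scheme
  nr <- cfg$processing$noise_region
  hwhm <- cfg$detection$ref_hwhm
  sums <- lapply(regions[c("mosh", "moah", "other")], function(reg) {
    res <- to_mass_fraction(quantify(spec, reg, eretic,
                                     normalize_by_ns_rg = normalize_by_ns_rg),
                            prep)
    res$lod_mass_fraction <- estimate_lod(spec, reg, eretic, prep, nr, hwhm)
    # sum parameters are gated on the LOD of their own window
    res$detected <- res$mass_fraction >= res$lod_mass_fraction
    if (!res$detected) res$mass_fraction <- NA_real_
    res
  })
  pah <- quantify_pah4(spec, eretic, prep, regions, nr, hwhm,
                       normalize_by_ns_rg = normalize_by_ns_rg)
  c(sums, pah)
}

result_record <- function(res) {
  list(analyte = res$analyte,
       absolute_integral = res$absolute_integral,
       concentration_g_l = res$concentration,
       mass_fraction_g_100g = if (is.na(res$mass_fraction)) NULL else res$mass_fraction,
       lod_g_100g = res$lod_mass_fraction,
       detected = res$detected,
       display = format_mass_fraction(res))
}

#' Run a measurement series end-to-end
#'
#' Processes the quantref spectrum (establishing the ERETIC factor), every
#' sample (saturates/aromatics/other sum parameters plus the four PAH4
#' targets, each with its detection limit), and the control solution (whose
#' recovery must fall inside 100 +/- 5 % for the series to be valid).
#' Reports are written as `report.json` (source of truth), `report.csv` and
#' a human-readable `report.txt`; reruns on identical inputs produce
#' byte-identical JSON. Samples without preparation metadata are skipped
#' with a logged reason. A failed control gate still produces a report, but
#' it is marked INVALID and the returned status is nonzero.
#'
#' @param manifest A [series_manifest()] or path to a manifest YAML.
#' @param config A [validate_config()] result, raw list, YAML path or `NULL`.
#' @param out_dir Output directory (`NULL` writes no files).
#' @param allow_missing_control Process a series lacking a control spectrum.
#' @param normalize_by_ns_rg Normalize integrals by scans x receiver gain.
#' @param reference Run TMS referencing during processing (default TRUE).
#' @return The report list, invisibly, with attribute `status` (0 = valid,
#'   1 = control gate failed).
#' @export
run_series <- function(manifest, config = NULL, out_dir = NULL,
                       allow_missing_control = FALSE,
                       normalize_by_ns_rg = FALSE, reference = TRUE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "series_manifest"))
  cfg <- if (inherits(config, "pulcon_config")) config else validate_config(config)
  if (is.na(manifest$control_path) && !allow_missing_control)
    stop("manifest has no control spectrum; a series is only valid with a ",
         "control measured last (use allow_missing_control = TRUE to override)",
         call. = FALSE)
  pc <- cfg$processing_config
  process_file <- function(path) {
    x <- read_jcamp(path)
    process_spectrum(x, pc, reference = reference)
  }
  quantref <- process_file(manifest$quantref_path)
  eretic <- eretic_from_quantref(quantref,
                                 quantref_recipe(cfg$quantref$tcnb_conc,
                                                 cfg$quantref$eb_conc),
                                 cfg$region_scheme,
                                 spread_tol = cfg$quantref$spread_tol,
                                 normalize_by_ns_rg = normalize_by_ns_rg)
  sample_reports <- list()
  for (i in seq_len(nrow(manifest$samples))) {
    s <- manifest$samples[i, ]
    if (is.na(s$sample_mass) || is.na(s$solution_volume)) {
      sample_reports[[i]] <- list(sample_id = s$sample_id,
                                  skipped = "missing preparation metadata (sample_mass/solution_volume)")
      next
    }
    prep <- sample_prep(s$sample_mass, s$solution_volume)
    spec <- process_file(s$path)
    results <- quantify_sample(spec, eretic, prep, cfg, normalize_by_ns_rg)
    sample_reports[[i]] <- list(
      sample_id = s$sample_id,
      category = if (is.na(s$category)) NULL else s$category,
      sample_mass_mg = s$sample_mass,
      solution_volume_ml = s$solution_volume,
      processing_log = spec$processing_log,
      results = lapply(results, result_record))
  }
  control <- NULL
  if (!is.na(manifest$control_path)) {
    cspec <- process_file(manifest$control_path)
    control <- control_recovery(cspec, eretic, cfg$region_scheme,
                                nominal_conc = cfg$control$nominal_conc,
                                force = TRUE,
                                normalize_by_ns_rg = normalize_by_ns_rg)
  }
  valid <- eretic$valid && (is.null(control) || control$passed)
  status <- if (valid) 0L else 1L
  echo <- cfg[setdiff(names(cfg), c("processing_config", "region_scheme"))]
  report <- list(
    tool = paste0("pulcon ", as.character(utils::packageVersion("pulcon"))),
    series_id = manifest$series_id,
    valid = valid,
    config = echo,
    config_hash = config_hash(echo),
    region_scheme_version = attr(cfg$region_scheme, "version"),
    eretic = list(value = eretic$value,
                  per_signal = as.list(eretic$per_signal),
                  spread = eretic$spread, valid = eretic$valid),
    qc = list(control = if (is.null(control)) NULL else
      list(nominal_mg_l = control$nominal_conc,
           measured_mg_l = control$measured_conc,
           recovery_percent = control$recovery,
           passed = control$passed),
      missing_control = is.null(control)),
    samples = sample_reports)
  if (!is.null(out_dir)) write_series_report(report, out_dir)
  attr(report, "status") <- status
  invisible(report)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_series_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  rows <- do.call(rbind, lapply(report$samples, function(s) {
    if (!is.null(s$skipped))
      return(data.frame(sample_id = s$sample_id, analyte = NA, display = NA,
                        concentration_g_l = NA, lod_g_100g = NA,
                        skipped = s$skipped))
    do.call(rbind, lapply(s$results, function(r)
      data.frame(sample_id = s$sample_id, analyte = r$analyte,
                 display = r$display,
                 concentration_g_l = r$concentration_g_l,
                 lod_g_100g = r$lod_g_100g, skipped = NA)))
  }))
  utils::write.csv(rows, file.path(out_dir, "report.csv"), row.names = FALSE)
  writeLines(format_series_report(report), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

# Text rendering of a report (every number re-read from the JSON structure).
format_series_report <- function(report) {
  analytes <- c(mosh = "MOSH", moah = "MOAH", other = "Other compounds",
                benz_a_anthracene = "Benz[a]anthracene",
                benzo_a_pyrene = "Benzo[a]pyrene",
                chrysene = "Chrysene",
                benzo_b_fluoranthene = "Benzo[b]fluoranthene")
  hdr <- sprintf("Series %s  [%s]", report$series_id,
                 if (report$valid) "VALID" else "INVALID")
  lines <- c(hdr, strrep("=", nchar(hdr)),
             sprintf("ERETIC factor: %.6g (spread %.2f%%, %s)",
                     report$eretic$value, 100 * report$eretic$spread,
                     if (report$eretic$valid) "valid" else "INVALID"),
             "")
  widths <- c(18, pmax(nchar(analytes) + 2, 14))
  row_fmt <- function(cells) paste(mapply(formatC, cells, width = widths,
                                          flag = "-"), collapse = "")
  lines <- c(lines, row_fmt(c("Sample", unname(analytes))),
             strrep("-", sum(widths)))
  for (s in report$samples) {
    if (!is.null(s$skipped)) {
      lines <- c(lines, sprintf("%-18s SKIPPED: %s", s$sample_id, s$skipped))
      next
    }
    cells <- vapply(names(analytes), function(a)
      s$results[[a]]$display %||% "-", character(1))
    lines <- c(lines, row_fmt(c(s$sample_id, cells)))
  }
  lines <- c(lines, "", "All values g/100 g; n.d. = not detectable below the listed LOD.")
  if (!is.null(report$qc$control)) {
    qc <- report$qc$control
    lines <- c(lines, sprintf(
      "Control: %.0f mg/L nominal, %.1f mg/L measured, recovery %.1f%% [%s]",
      qc$nominal_mg_l, qc$measured_mg_l, qc$recovery_percent,
      if (qc$passed) "PASSED" else "FAILED"))
  } else {
    lines <- c(lines, "Control: MISSING (processed with override)")
  }
  lines
}
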