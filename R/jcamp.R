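# JCAMP-DX 1D NMR reader/writer.
#
# Read: AFFN and ASDF (SQZ/DIF/DUP) encoded XYDATA blocks for processed real
# spectra, and NTUPLES blocks with real/imaginary pages for FIDs.
# Write: AFFN only; compressed output is not required by any consumer.

# --- ASDF pseudo-digit tables -------------------------------------------------
# SQZ: @=0, A..I = 1..9, a..i = -1..-9 (starts a new absolute value)
# DIF: %=0, J..R = 1..9, j..r = -1..-9 (starts a difference from last value)
# DUP: S..Z = 1..8, s = 9             (repeats the previous value/difference)
.sqz_chars <- c("@", LETTERS[1:9], letters[1:9])
.sqz_vals  <- c(0, 1:9, -(1:9))
.dif_chars <- c("%", LETTERS[10:18], letters[10:18])
.dif_vals  <- c(0, 1:9, -(1:9))
.dup_chars <- c(LETTERS[19:26], "s")
.dup_vals  <- c(1:8, 9)

# Decode one data line into numeric values (x check value first).
# A line containing any unambiguous pseudo-digit is treated as ASDF, in which
# case 'E'/'e' are SQZ digits (5/-5): the standard does not allow exponential
# AFFN inside ASDF lines. Lines without pseudo-digits are plain AFFN and may
# use exponent notation.
# Returns list(values, started_in_dif, ended_in_dif): in DIF mode the first
# ordinate of a continuation line is a check value duplicating the last
# ordinate of the previous line and must be dropped by the caller.
decode_data_line <- function(line) {
  line <- sub("\\$\\$.*$", "", line)  # strip comments
  is_asdf <- grepl("[@A-DF-Za-df-z%]", line)
  if (!is_asdf) {
    toks <- strsplit(trimws(line), "[ \t,;]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("malformed data token: ", toks[which(is.na(vals))[1]], call. = FALSE)
    return(list(values = vals, started_in_dif = FALSE, ended_in_dif = FALSE))
  }
  # split so every pseudo-digit starts a token
  marked <- gsub("([@A-Za-z%])", " \\1", line)
  toks <- strsplit(trimws(marked), "[ \t,;]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(list(values = numeric(0), started_in_dif = FALSE,
                                 ended_in_dif = FALSE))
  vals <- numeric(0)
  last <- NA_real_         # last ordinate value
  last_delta <- NA_real_   # last difference (for DUP after DIF)
  last_mode <- "none"      # "value" or "dif"
  started_in_dif <- FALSE
  first_tok <- TRUE
  for (tok in toks) {
    c1 <- substr(tok, 1, 1)
    rest <- substr(tok, 2, nchar(tok))
    if (c1 %in% .sqz_chars && !grepl("^[0-9+.-]", tok)) {
      digit <- .sqz_vals[match(c1, .sqz_chars)]
      v <- as.numeric(paste0(if (digit < 0) "-" else "", abs(digit), rest))
      if (is.na(v)) stop("malformed ASDF token: ", tok, call. = FALSE)
      last <- v; last_mode <- "value"
      vals <- c(vals, v)
    } else if (c1 %in% .dif_chars) {
      digit <- .dif_vals[match(c1, .dif_chars)]
      dlt <- as.numeric(paste0(if (digit < 0) "-" else "", abs(digit), rest))
      if (is.na(dlt)) stop("malformed ASDF token: ", tok, call. = FALSE)
      if (is.na(last)) stop("DIF token without preceding value: ", tok, call. = FALSE)
      if (first_tok) started_in_dif <- TRUE
      last <- last + dlt; last_delta <- dlt; last_mode <- "dif"
      vals <- c(vals, last)
    } else if (c1 %in% .dup_chars) {
      count <- .dup_vals[match(c1, .dup_chars)]
      count <- as.numeric(paste0(count, rest))
      # DUP count includes the original occurrence -> repeat count-1 more times
      reps <- count - 1L
      if (reps < 0 || last_mode == "none")
        stop("malformed DUP token: ", tok, call. = FALSE)
      if (last_mode == "dif") {
        for (i in seq_len(reps)) { last <- last + last_delta; vals <- c(vals, last) }
      } else {
        vals <- c(vals, rep(last, reps))
      }
    } else {
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) stop("malformed data token: ", tok, call. = FALSE)
      last <- v; last_mode <- "value"
      vals <- c(vals, v)
    }
    first_tok <- FALSE
  }
  list(values = vals, started_in_dif = started_in_dif,
       ended_in_dif = last_mode == "dif")
}

# Decode a block of data lines in (X++(Y..Y)) form to a numeric y vector.
decode_xy_block <- function(lines) {
  y <- numeric(0)
  prev_ended_dif <- FALSE
  for (ln in lines) {
    if (!nzchar(trimws(sub("\\$\\$.*$", "", ln)))) next
    dec <- decode_data_line(ln)
    v <- dec$values
    if (length(v) < 2L) next
    v <- v[-1L]  # drop leading x check value
    if (prev_ended_dif) {
      # first ordinate is a y check value repeating the previous line's last y
      if (length(y) && length(v) &&
          is.finite(v[1]) && abs(v[1] - y[length(y)]) > 1e-6 * max(1, abs(y[length(y)])))
        warning("JCAMP DIF y-check mismatch; keeping decoded value", call. = FALSE)
      v <- v[-1L]
    }
    y <- c(y, v)
    prev_ended_dif <- dec$ended_in_dif
  }
  y
}

# Parse the LDR (labeled data record) structure of a JCAMP-DX file.
# Returns a list of records: list(label, value, data = character lines).
parse_ldrs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  for (ln in lines) {
    if (startsWith(ln, "##")) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0)
        stop("malformed JCAMP label line (missing '='): ", ln, call. = FALSE)
      label <- substr(ln, 3, eq - 1)
      value <- trimws(substr(ln, eq + 1, nchar(ln)))
      cur <- list(label = label, value = value, data = character())
    } else if (!is.null(cur)) {
      cur$data <- c(cur$data, ln)
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  recs
}

# Canonical label: uppercase, spaces/dashes/underscores/slashes removed.
canon_label <- function(x) toupper(gsub("[ _/-]", "", x))

ldr_value <- function(recs, label, default = NULL) {
  key <- canon_label(label)
  for (r in recs) if (canon_label(r$label) == key) return(r$value)
  default
}

ldr_num <- function(recs, label, default = NA_real_) {
  v <- ldr_value(recs, label)
  if (is.null(v)) return(default)
  out <- suppressWarnings(as.numeric(sub(",.*$", "", v)))
  if (is.na(out)) default else out
}

#' Read a JCAMP-DX file
#'
#' Reads 1D NMR data in JCAMP-DX format. Processed real spectra stored as
#' `XYDATA=(X++(Y..Y))` blocks (AFFN or SQZ/DIF/DUP compressed) return a
#' [spectrum1d()]; time-domain data stored as an NTUPLES block with
#' real/imaginary pages return a [fid_record()]. The ppm axis of a processed
#' spectrum is reconstructed from `FIRSTX`, `LASTX` and `NPOINTS`.
#'
#' When `NS` (scans) or `RG` (receiver gain) are absent they default to 1
#' with a warning, because external (PULCON) calibration across spectra is
#' only valid when acquisition parameters are constant or normalized.
#'
#' @param path Path to a JCAMP-DX file.
#' @return A [spectrum1d()] or [fid_record()].
#' @seealso [write_jcamp()]
#' @export
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- parse_ldrs(path)
  if (!length(recs)) stop("not a JCAMP-DX file: ", path, call. = FALSE)
  dtype <- toupper(ldr_value(recs, "DATATYPE", ""))
  freq <- ldr_num(recs, ".OBSERVEFREQUENCY")
  if (is.na(freq)) freq <- ldr_num(recs, "$SFO1")
  if (is.na(freq))
    stop("metadata error: missing observe frequency (##.OBSERVE FREQUENCY=)",
         call. = FALSE)
  scans <- ldr_num(recs, "$NS")
  rg <- ldr_num(recs, "$RG")
  if (is.na(scans)) {
    warning("scans (##$NS) absent; defaulting to 1 - PULCON assumes constant acquisition",
            call. = FALSE)
    scans <- 1
  }
  if (is.na(rg)) {
    warning("receiver gain (##$RG) absent; defaulting to 1 - PULCON assumes constant acquisition",
            call. = FALSE)
    rg <- 1
  }
  series_id <- ldr_value(recs, "$SERIESID", NA_character_)
  sample_id <- ldr_value(recs, "$SAMPLEID", NA_character_)

  has_ntuples <- !is.null(ldr_value(recs, "NTUPLES"))
  if (grepl("FID", dtype) || has_ntuples)
    return(read_jcamp_fid(recs, freq, scans, rg, series_id, sample_id))

  # processed real spectrum: XYDATA block
  xy <- NULL
  for (r in recs) if (canon_label(r$label) == "XYDATA") { xy <- r; break }
  if (is.null(xy))
    stop("unsupported block: no XYDATA or NTUPLES data found", call. = FALSE)
  firstx <- ldr_num(recs, "FIRSTX")
  lastx <- ldr_num(recs, "LASTX")
  npts <- ldr_num(recs, "NPOINTS")
  yfac <- ldr_num(recs, "YFACTOR", 1)
  xfac <- ldr_num(recs, "XFACTOR", 1)
  if (is.na(firstx) || is.na(lastx) || is.na(npts))
    stop("metadata error: FIRSTX/LASTX/NPOINTS required for XYDATA", call. = FALSE)
  y <- decode_xy_block(xy$data) * yfac
  if (length(y) != npts)
    stop(sprintf("XYDATA decoded %d points but NPOINTS=%d", length(y), npts),
         call. = FALSE)
  ppm <- seq(firstx * xfac, lastx * xfac, length.out = npts)
  spectrum1d(ppm, y, spectrometer_freq = freq, scans = scans,
             receiver_gain = rg, series_id = series_id, sample_id = sample_id,
             processing_log = sprintf("read_jcamp(%s)", basename(path)))
}

# Read an NTUPLES FID: pages with (X++(R..R)) and (X++(I..I)) data tables.
read_jcamp_fid <- function(recs, freq, scans, rg, series_id, sample_id) {
  re <- NULL; im <- NULL
  current_sym <- NULL
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    lbl <- canon_label(r$label)
    if (lbl == "PAGE") current_sym <- NULL
    if (lbl == "DATATABLE") {
      sym <- if (grepl("R\\.\\.R", r$value)) "R"
             else if (grepl("I\\.\\.I", r$value)) "I" else NA
      vals <- decode_xy_block(r$data)
      if (identical(sym, "R")) re <- vals
      else if (identical(sym, "I")) im <- vals
    }
  }
  if (is.null(re) && !is.null(im))
    stop("unsupported block: imaginary-only FID data", call. = FALSE)
  if (is.null(re))
    stop("unsupported block: no FID data table found", call. = FALSE)
  if (is.null(im)) im <- rep(0, length(re))
  if (length(im) != length(re))
    stop("real and imaginary FID pages differ in length", call. = FALSE)
  # dwell time from the TIME variable FIRST/LAST, or an explicit label
  dwell <- ldr_num(recs, "$DWELLTIME")
  if (is.na(dwell)) {
    first_t <- ldr_num(recs, "FIRST")
    last_v <- ldr_value(recs, "LAST")
    last_t <- if (!is.null(last_v))
      suppressWarnings(as.numeric(strsplit(last_v, ",")[[1]][1])) else NA_real_
    if (!is.na(first_t) && !is.na(last_t) && length(re) > 1)
      dwell <- (last_t - first_t) / (length(re) - 1)
  }
  if (is.na(dwell) || dwell <= 0)
    stop("metadata error: cannot determine dwell time for FID", call. = FALSE)
  fid_record(complex(real = re, imaginary = im), dwell_time = dwell,
             spectrometer_freq = freq, scans = scans, receiver_gain = rg,
             center_ppm = ldr_num(recs, "$CENTERPPM", 0),
             series_id = series_id, sample_id = sample_id)
}

fmt_affn <- function(x) formatC(x, format = "e", digits = 9)

#' Write a spectrum or FID to JCAMP-DX
#'
#' Writes AFFN-encoded JCAMP-DX readable by [read_jcamp()]. A [spectrum1d()]
#' becomes an `XYDATA=(X++(Y..Y))` block (real part only); a [fid_record()]
#' becomes an NTUPLES block with real and imaginary pages. Round trips
#' preserve intensities to better than 1e-6 relative together with the
#' acquisition metadata.
#'
#' @param x A [spectrum1d()] or [fid_record()].
#' @param path Output file path.
#' @param title Title line (default from `sample_id`).
#' @return `path`, invisibly.
#' @export
write_jcamp <- function(x, path, title = NULL) UseMethod("write_jcamp")

jcamp_meta_lines <- function(x) {
  c(sprintf("##.OBSERVE FREQUENCY= %.6f", x$spectrometer_freq),
    "##.OBSERVE NUCLEUS= ^1H",
    sprintf("##$NS= %d", x$scans),
    sprintf("##$RG= %s", format(x$receiver_gain)),
    if (!is.na(x$series_id)) sprintf("##$SERIESID= %s", x$series_id),
    if (!is.na(x$sample_id)) sprintf("##$SAMPLEID= %s", x$sample_id))
}

# y values written 6 per line, preceded by the x check value (point index
# scale via XFACTOR is not used; x is written in ppm).
affn_data_lines <- function(xvals, yvals, per_line = 6L) {
  n <- length(yvals)
  starts <- seq(1L, n, by = per_line)
  vapply(starts, function(s) {
    e <- min(s + per_line - 1L, n)
    paste(c(fmt_affn(xvals[s]), fmt_affn(yvals[s:e])), collapse = " ")
  }, character(1))
}

#' @rdname write_jcamp
#' @export
write_jcamp.spectrum1d <- function(x, path, title = NULL) {
  if (length(x$intensity) == 0L) stop("empty intensity vector", call. = FALSE)
  n <- length(x$ppm)
  lines <- c(
    sprintf("##TITLE= %s", title %||% (if (is.na(x$sample_id)) "spectrum" else x$sample_id)),
    "##JCAMP-DX= 5.01",
    "##DATA TYPE= NMR SPECTRUM",
    "##DATA CLASS= XYDATA",
    "##ORIGIN= pulcon",
    "##OWNER= pulcon",
    jcamp_meta_lines(x),
    "##XUNITS= PPM",
    "##YUNITS= ARBITRARY UNITS",
    "##XFACTOR= 1",
    "##YFACTOR= 1",
    sprintf("##FIRSTX= %s", fmt_affn(x$ppm[1])),
    sprintf("##LASTX= %s", fmt_affn(x$ppm[n])),
    sprintf("##FIRSTY= %s", fmt_affn(x$intensity[1])),
    sprintf("##NPOINTS= %d", n),
    "##XYDATA= (X++(Y..Y))",
    affn_data_lines(x$ppm, x$intensity),
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_jcamp
#' @export
write_jcamp.fid_record <- function(x, path, title = NULL) {
  n <- length(x$points)
  tmax <- (n - 1) * x$dwell_time
  tvals <- (seq_len(n) - 1) * x$dwell_time
  re <- Re(x$points); im <- Im(x$points)
  lines <- c(
    sprintf("##TITLE= %s", title %||% (if (is.na(x$sample_id)) "fid" else x$sample_id)),
    "##JCAMP-DX= 6.00",
    "##DATA TYPE= NMR FID",
    "##DATA CLASS= NTUPLES",
    "##ORIGIN= pulcon",
    "##OWNER= pulcon",
    jcamp_meta_lines(x),
    sprintf("##$DWELLTIME= %s", fmt_affn(x$dwell_time)),
    sprintf("##$CENTERPPM= %s", fmt_affn(x$center_ppm)),
    "##NTUPLES= NMR FID",
    "##VAR_NAME= TIME, FID/REAL, FID/IMAG",
    "##SYMBOL= X, R, I",
    "##VAR_TYPE= INDEPENDENT, DEPENDENT, DEPENDENT",
    "##VAR_FORM= AFFN, AFFN, AFFN",
    sprintf("##VAR_DIM= %d, %d, %d", n, n, n),
    "##UNITS= SECONDS, ARBITRARY UNITS, ARBITRARY UNITS",
    sprintf("##FIRST= 0, %s, %s", fmt_affn(re[1]), fmt_affn(im[1])),
    sprintf("##LAST= %s, %s, %s", fmt_affn(tmax), fmt_affn(re[n]), fmt_affn(im[n])),
    "##FACTOR= 1, 1, 1",
    "##PAGE= N=1",
    "##DATA TABLE= (X++(R..R)), XYDATA",
    affn_data_lines(tvals, re),
    "##PAGE= N=2",
    "##DATA TABLE= (X++(I..I)), XYDATA",
    affn_data_lines(tvals, im),
    "##END NTUPLES= NMR FID",
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
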