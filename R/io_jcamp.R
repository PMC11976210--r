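# JCAMP-DX import/export and tabular serialisation.
#
# FIDs are written in an NTUPLES complex-FID dialect with AFFN (plain
# decimal) data tables: one page for the real quadrature and one for the
# imaginary, each as (X++(Y..Y)) pairs of "time value" lines.  The reader
# parses exactly this dialect, validating the header bookkeeping
# (NPOINTS vs data length, dwell vs first/last X) and failing with the
# offending record named.

#' Write an FID as JCAMP-DX
#'
#' @param fid an \code{nmr_fid}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_fid_jcamp <- function(fid, path) {
  stopifnot(inherits(fid, "nmr_fid"))
  g <- fid$grid
  t <- fid_times(fid)
  num <- function(v) sprintf("%.12e", v)
  lines <- c(
    "##TITLE= craftnmr FID export",
    "##JCAMP-DX= 6.00",
    "##DATA TYPE= NMR FID",
    "##DATA CLASS= NTUPLES",
    "##ORIGIN= craftnmr",
    "##OWNER= craftnmr",
    sprintf("##.OBSERVE FREQUENCY= %s", num(g$spectrometer_mhz)),
    "##.OBSERVE NUCLEUS= ^19F",
    sprintf("##$CARRIERPPM= %s", num(g$carrier_ppm)),
    sprintf("##$DWELL= %s", num(g$dwell_s)),
    sprintf("##$T0= %s", num(fid$t0_s)),
    sprintf("##$NSCANS= %d", fid$n_scans),
    sprintf("##$PROVENANCE= %s", fid$provenance),
    sprintf("##NPOINTS= %d", g$n_points),
    sprintf("##FIRSTX= %s", num(t[1])),
    sprintf("##LASTX= %s", num(t[length(t)])),
    "##NTUPLES= NMR FID",
    "##VAR_NAME= TIME, FID/REAL, FID/IMAG",
    "##SYMBOL= X, R, I",
    "##VAR_TYPE= INDEPENDENT, DEPENDENT, DEPENDENT",
    "##VAR_FORM= AFFN, AFFN, AFFN",
    sprintf("##VAR_DIM= %d, %d, %d", g$n_points, g$n_points, g$n_points),
    "##UNITS= SECONDS, ARBITRARY UNITS, ARBITRARY UNITS",
    "##PAGE= R",
    "##DATA TABLE= (X++(R..R)), XYDATA",
    paste(num(t), num(Re(fid$samples))),
    "##PAGE= I",
    "##DATA TABLE= (X++(I..I)), XYDATA",
    paste(num(t), num(Im(fid$samples))),
    "##END NTUPLES= NMR FID",
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}

jcamp_field <- function(lines, key, required = TRUE) {
  pat <- paste0("^", gsub("([.$^])", "\\\\\\1", key), "=")
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) == 0L) {
    if (required) stop("JCAMP parse error: missing record ", key)
    return(NA_character_)
  }
  trimws(sub(pat, "", hit[1]))
}

#' Read an FID from JCAMP-DX
#'
#' Reads the NTUPLES complex-FID dialect written by
#' \code{\link{write_fid_jcamp}}.  A write-read round trip is lossless to
#' well below 1e-8 relative.  Malformed files produce a parse or
#' validation error naming the offending record.
#'
#' @param path a JCAMP-DX file.
#' @return an \code{nmr_fid}.
#' @export
read_fid_jcamp <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(grepl("^##TITLE=", lines)))
    stop("JCAMP parse error: missing record ##TITLE")
  mhz <- as.numeric(jcamp_field(lines, "##.OBSERVE FREQUENCY"))
  carrier <- as.numeric(jcamp_field(lines, "##$CARRIERPPM"))
  dwell <- as.numeric(jcamp_field(lines, "##$DWELL"))
  t0 <- as.numeric(jcamp_field(lines, "##$T0"))
  nscans <- as.integer(jcamp_field(lines, "##$NSCANS"))
  prov <- jcamp_field(lines, "##$PROVENANCE")
  npts <- as.integer(jcamp_field(lines, "##NPOINTS"))
  firstx <- as.numeric(jcamp_field(lines, "##FIRSTX"))
  lastx <- as.numeric(jcamp_field(lines, "##LASTX"))
  if (any(is.na(c(mhz, carrier, dwell, t0, nscans, npts, firstx, lastx))))
    stop("JCAMP parse error: non-numeric header record")
  if (npts < 1) stop("JCAMP validation error: ##NPOINTS must be positive")
  expect_last <- t0 + (npts - 1) * dwell
  tol <- max(1e-9, 1e-6 * dwell * npts)
  if (abs(firstx - t0) > tol)
    stop("JCAMP validation error: ##FIRSTX inconsistent with ##$T0")
  if (abs(lastx - expect_last) > tol)
    stop("JCAMP validation error: ##LASTX inconsistent with ",
         "##$DWELL and ##NPOINTS")
  read_page <- function(sym) {
    pg <- which(grepl(paste0("^##PAGE= *", sym, " *$"), lines))
    if (length(pg) != 1L)
      stop("JCAMP parse error: missing record ##PAGE= ", sym)
    i <- pg + 1L
    if (i > length(lines) || !grepl("^##DATA TABLE=", lines[i]))
      stop("JCAMP parse error: missing record ##DATA TABLE (page ", sym, ")")
    i <- i + 1L
    vals <- numeric(0)
    xs <- numeric(0)
    while (i <= length(lines) && !grepl("^##", lines[i])) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(parts) < 2L)
        stop("JCAMP parse error: malformed data line in page ", sym,
             ": '", lines[i], "'")
      xs <- c(xs, as.numeric(parts[1]))
      vals <- c(vals, as.numeric(parts[-1]))
      i <- i + 1L
    }
    if (length(vals) != npts)
      stop("JCAMP validation error: page ", sym, " has ", length(vals),
           " points, ##NPOINTS says ", npts)
    if (anyNA(vals) || anyNA(xs))
      stop("JCAMP parse error: non-numeric datum in page ", sym)
    list(x = xs, y = vals)
  }
  re <- read_page("R")
  im <- read_page("I")
  grid <- acq_grid(dwell, npts, mhz, carrier)
  new_fid(complex(real = re$y, imaginary = im$y), grid, n_scans = nscans,
          provenance = prov, t0_s = t0)
}

#' Serialise an amplitude-frequency table as CSV
#'
#' Fixed header: component_id, frequency_hz, ppm, amplitude,
#' decay_rate_s-1, fwhm_hz, phase_rad, se_frequency_hz, se_amplitude,
#' se_decay_rate, se_phase, band_id.
#'
#' @param table a \code{craft} fit or its components \code{data.frame}.
#' @param path destination CSV.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(table, path) {
  comp <- if (inherits(table, "craft")) table$components else
    as.data.frame(table)
  out <- data.frame(component_id = seq_len(nrow(comp)))
  cols <- c(frequency_hz = "frequency_hz", ppm = "ppm",
            amplitude = "amplitude", `decay_rate_s-1` = "decay_rate",
            fwhm_hz = "fwhm_hz", phase_rad = "phase_rad",
            se_frequency_hz = "se_frequency_hz",
            se_amplitude = "se_amplitude", se_decay_rate = "se_decay_rate",
            se_phase = "se_phase", band_id = "band_id")
  for (nm in names(cols))
    out[[nm]] <- if (cols[[nm]] %in% names(comp)) comp[[cols[[nm]]]] else NA
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a spectrum as two-column text or JCAMP-DX
#'
#' \code{write_spectrum_txt} writes "ppm real-intensity" pairs;
#' \code{write_spectrum_jcamp} writes a simple XYDATA JCAMP-DX spectrum
#' (real part).
#'
#' @param spectrum an \code{nmr_spectrum}.
#' @param path destination file.
#' @return \code{path}, invisibly.
#' @export
write_spectrum_txt <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  utils::write.table(
    data.frame(ppm = spectrum$ppm, intensity = Re(spectrum$intensities)),
    path, row.names = FALSE, col.names = c("ppm", "intensity"),
    quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_txt
#' @export
write_spectrum_jcamp <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  num <- function(v) sprintf("%.10e", v)
  lines <- c(
    "##TITLE= craftnmr spectrum export",
    "##JCAMP-DX= 6.00",
    "##DATA TYPE= NMR SPECTRUM",
    sprintf("##.OBSERVE FREQUENCY= %s", num(spectrum$grid$spectrometer_mhz)),
    "##XUNITS= HZ",
    "##YUNITS= ARBITRARY UNITS",
    sprintf("##NPOINTS= %d", length(spectrum$freq_hz)),
    sprintf("##FIRSTX= %s", num(spectrum$freq_hz[1])),
    sprintf("##LASTX= %s", num(spectrum$freq_hz[length(spectrum$freq_hz)])),
    "##XYDATA= (XY..XY)",
    paste(num(spectrum$freq_hz), num(Re(spectrum$intensities))),
    "##END="
  )
  writeLines(lines, path)
  invisible(path)
}
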