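#' Spectrum readers and writers
#'
#' Two plain-text exchange formats are supported: two-column CSV
#' (`ppm,intensity` with header) and JCAMP-DX (AFFN `##XYDATA=(X++(Y..Y))`
#' blocks, plus the NTUPLES `##DATA TABLE= (X++(Y..Y))` dialect on read).
#' Spectra are normalized to the canonical high-to-low ppm orientation on
#' read.
#'
#' @name io-module
NULL

#' Read a spectrum from disk
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"jcamp"`.
#' @return A `spectrum`; JCAMP metadata (title, observe frequency, n_scans)
#'   is passed through into `meta` when present. A missing frequency gives a
#'   warning and is left unset.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") .read_csv_spectrum(path) else .read_jcamp_spectrum(path)
}

.read_csv_spectrum <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop("malformed CSV '", path, "': ",
                                          conditionMessage(e)))
  if (ncol(df) < 2L) stop("CSV '", path, "' must have two columns (ppm, intensity)")
  new_spectrum(df[[1]], df[[2]], meta = list(source = path))
}

.read_jcamp_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- list(source = path)
  get_label <- function(label) {
    pat <- paste0("^##\\$?", label, "\\s*=\\s*")
    hit <- grep(pat, lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(pat, "", hit[1], ignore.case = TRUE))
  }
  title <- get_label("TITLE"); if (!is.null(title)) meta$title <- title
  freq <- get_label("\\.OBSERVE FREQUENCY") %||% get_label("OBSERVEFREQUENCY")
  if (!is.null(freq)) {
    meta$spectrometer_freq <- as.numeric(freq)
  } else {
    warning("JCAMP file '", path, "' carries no observe frequency; left unset")
  }
  ns <- get_label("NS") %||% get_label("NSCANS")
  if (!is.null(ns)) meta$n_scans <- as.integer(as.numeric(ns))

  xfac <- as.numeric(get_label("XFACTOR") %||% "1")
  yfac <- as.numeric(get_label("YFACTOR") %||% "1")

  start <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) {
    start <- grep("^##DATA TABLE\\s*=.*X\\+\\+\\(Y\\.\\.Y\\)", lines,
                  ignore.case = TRUE)
  }
  if (!length(start)) stop("JCAMP file '", path, "' has no XYDATA or DATA TABLE block")
  start <- start[1]
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start]
  end <- if (length(stop_at)) min(stop_at) - 1L else length(lines)
  block <- lines[(start + 1L):end]
  block <- block[nzchar(trimws(block))]

  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_along(block)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(block[i]),
                                                 "[ \t,]+")[[1]]))
    if (any(is.na(vals)) || length(vals) < 2L) {
      stop(sprintf("JCAMP parse error in '%s' at data line %d: '%s'",
                   path, i, block[i]))
    }
    x0 <- vals[1]; yv <- vals[-1]
    xs <- c(xs, x0); ys <- c(ys, yv[1])
    if (length(yv) > 1L) {
      # subsequent ordinates advance x by the per-line spacing
      xs <- c(xs, rep(NA_real_, length(yv) - 1L))
      ys <- c(ys, yv[-1])
    }
  }
  # fill implied abscissae from FIRSTX/LASTX/NPOINTS when multiple Y per line
  if (anyNA(xs)) {
    firstx <- as.numeric(get_label("FIRSTX"))
    lastx <- as.numeric(get_label("LASTX"))
    npts <- as.numeric(get_label("NPOINTS"))
    if (any(is.na(c(firstx, lastx, npts)))) {
      stop("JCAMP file '", path, "' needs FIRSTX/LASTX/NPOINTS for multi-Y lines")
    }
    xs <- seq(firstx, lastx, length.out = npts)
    if (length(ys) != npts) {
      stop(sprintf("JCAMP file '%s': NPOINTS=%d but %d ordinates found",
                   path, npts, length(ys)))
    }
  }
  new_spectrum(xs * xfac, ys * yfac, meta = meta)
}

#' Write a spectrum to disk
#'
#' @param spec A `spectrum`.
#' @param path Output path.
#' @param format `"auto"`, `"csv"` or `"jcamp"`. Round trips preserve axis
#'   and intensities to better than 1e-9 relative.
#' @param title Title recorded in JCAMP output.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, format = c("auto", "csv", "jcamp"),
                           title = "lfnmr spectrum") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") {
    utils::write.csv(data.frame(ppm = format(spec$axis, digits = 17, trim = TRUE),
                                intensity = format(spec$intensities, digits = 17,
                                                   trim = TRUE)),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    hdr <- c(
      paste0("##TITLE=", title),
      "##JCAMP-DX=5.00",
      "##DATA TYPE=NMR SPECTRUM",
      "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
      if (!is.null(spec$meta$spectrometer_freq)) {
        paste0("##.OBSERVE FREQUENCY=", format(spec$meta$spectrometer_freq,
                                               digits = 12))
      },
      if (!is.null(spec$meta$n_scans)) paste0("##NS=", spec$meta$n_scans),
      paste0("##FIRSTX=", format(spec$axis[1], digits = 17)),
      paste0("##LASTX=", format(spec$axis[length(spec$axis)], digits = 17)),
      paste0("##NPOINTS=", length(spec$axis)),
      "##XFACTOR=1", "##YFACTOR=1",
      "##XYDATA=(X++(Y..Y))")
    writeLines(hdr, con)
    writeLines(paste(format(spec$axis, digits = 17, trim = TRUE),
                     format(spec$intensities, digits = 17, trim = TRUE)), con)
    writeLines("##END=", con)
  }
  invisible(path)
}
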