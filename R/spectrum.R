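#' Spectrum container and ppm axis helpers
#'
#' A `spectrum` holds a ppm axis (canonical orientation: high to low ppm, the
#' NMR display convention and the direction of cumulative integration used for
#' metabolite bounds), an intensity vector of the same length, per-species
#' component vectors where available (simulated spectra), and acquisition
#' metadata.
#'
#' @name spectrum-class
NULL

#' Construct a ppm axis
#'
#' @param from High-ppm end of the axis (default 10).
#' @param to Low-ppm end (default -2.2, covering the [-2, -1] ppm noise
#'   region).
#' @param by Point spacing in ppm; the default 6.1487e-4 ppm matches the
#'   digital resolution of 80 MHz benchtop acquisitions.
#' @return Numeric vector, strictly decreasing.
#' @export
ppm_axis <- function(from = 10, to = -2.2, by = 6.1487e-4) {
  if (from <= to) stop("'from' must exceed 'to' (axis runs high to low ppm)")
  seq(from, to, by = -abs(by))
}

#' Construct a spectrum
#'
#' @param axis ppm grid, strictly monotone (reordered to high-to-low if
#'   ascending).
#' @param intensities Numeric vector, same length as `axis`.
#' @param components Optional named list of per-species intensity vectors that
#'   sum to `intensities`.
#' @param meta Named list of acquisition metadata (n_scans, profile,
#'   spectrometer_freq, scaling/alignment state, ...).
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(axis, intensities, components = NULL, meta = list()) {
  axis <- as.numeric(axis); intensities <- as.numeric(intensities)
  if (length(axis) != length(intensities)) {
    stop("axis and intensities must have the same length")
  }
  d <- diff(axis)
  if (all(d > 0)) {  # ascending input: flip to canonical orientation
    axis <- rev(axis); intensities <- rev(intensities)
    if (!is.null(components)) components <- lapply(components, rev)
  } else if (!all(d < 0)) {
    stop("axis must be strictly monotone")
  }
  structure(list(axis = axis, intensities = intensities,
                 components = components, meta = meta),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d points, %.4f to %.4f ppm\n",
              length(x$axis), x$axis[1], x$axis[length(x$axis)]))
  if (!is.null(x$components)) {
    cat("  components:", paste(names(x$components), collapse = ", "), "\n")
  }
  if (length(x$meta)) {
    keys <- intersect(c("n_scans", "profile", "scaling", "aligned",
                        "spectrometer_freq", "total_time"), names(x$meta))
    for (k in keys) cat(sprintf("  %s: %s\n", k, format(x$meta[[k]])))
  }
  invisible(x)
}

# Indices of axis points inside a closed ppm interval.
.interval_idx <- function(spec, interval) {
  which(spec$axis >= interval$low - 1e-12 & spec$axis <= interval$high + 1e-12)
}
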