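#' Reference-peak preprocessing: TSP fitting, alignment, scaling
#'
#' Spectra are referenced to the internal standard TSP: a single Lorentzian
#' plus constant baseline is least-squares fitted inside a window around
#' 0 ppm, the axis is shifted so the fitted centre sits at exactly 0.00 ppm
#' (intensities re-interpolated onto the canonical grid), and intensities are
#' scaled by the ratio of a reference spectrum's TSP integral to this
#' spectrum's, so that the fixed-concentration reference has constant
#' integrated intensity across a series.
#'
#' @name preprocessing-module
NULL

#' Fit the reference (TSP) peak
#'
#' Least-squares fit of `b + h / (1 + (2 (x - c) / w)^2)` within the window.
#' Non-convergence or a peak that does not rise above the residual scatter
#' yields a flagged (low-confidence) result rather than an error, since a
#' poor reference fit is a data property the caller must be able to inspect.
#'
#' @param spec A `spectrum`.
#' @param window [ppm_interval()]; default [-0.05, 0.05] ppm. Must contain at
#'   least 10 points.
#' @param min_height_snr Flag the fit when fitted height < this multiple of
#'   the residual RMSE (default 5).
#' @return Object of class `lorentzian_fit`: `centre` (ppm), `fwhm` (ppm),
#'   `area` (intensity x ppm), `height`, `baseline`, `fit_rmse`, `flagged`,
#'   `message`.
#' @export
fit_reference_peak <- function(spec, window = ppm_interval(-0.05, 0.05),
                               min_height_snr = 5) {
  idx <- .interval_idx(spec, window)
  if (length(idx) < 10L) stop("reference window must contain at least 10 points")
  x <- spec$axis[idx]; y <- spec$intensities[idx]

  b0 <- stats::median(y)
  h0 <- max(y) - b0
  c0 <- x[which.max(y)]
  w0 <- max(4 * abs(mean(diff(x))), 0.005)
  par0 <- c(h = h0, c = c0, w = w0, b = b0)

  resid_fn <- function(p) {
    y - (p[4] + p[1] / (1 + (2 * (x - p[2]) / p[3])^2))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid_fn,
                       lower = c(-Inf, min(x), 1e-6, -Inf),
                       upper = c(Inf, max(x), diff(range(x)) * 4, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  flagged <- FALSE; msg <- "ok"
  if (is.null(fit) || fit$info %in% c(0, 9)) {
    flagged <- TRUE
    msg <- "fit did not converge"
    p <- if (is.null(fit)) par0 else fit$par
  } else {
    p <- fit$par
  }
  rmse <- sqrt(mean(resid_fn(p)^2))
  if (!flagged && (p[1] <= 0 || p[1] < min_height_snr * rmse)) {
    flagged <- TRUE
    msg <- "no credible peak above residual scatter"
  }
  structure(list(centre = unname(p[2]), fwhm = unname(p[3]),
                 area = unname(pi * p[1] * p[3] / 2), height = unname(p[1]),
                 baseline = unname(p[4]), fit_rmse = rmse,
                 flagged = flagged, message = msg, window = window),
            class = "lorentzian_fit")
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("<lorentzian_fit> centre %.5f ppm, fwhm %.5f ppm, area %.4g%s\n",
              x$centre, x$fwhm, x$area,
              if (x$flagged) paste0("  [FLAGGED: ", x$message, "]") else ""))
  invisible(x)
}

#' Align a spectrum so its reference peak sits at 0.00 ppm
#'
#' @param spec A `spectrum`.
#' @param fit A non-flagged [fit_reference_peak()] result.
#' @param max_shift Sanity bound on the applied shift in ppm (default 0.1).
#' @return The aligned `spectrum` (intensities linearly re-interpolated onto
#'   the original grid; components shifted consistently).
#' @export
align_to_reference <- function(spec, fit, max_shift = 0.1) {
  stopifnot(inherits(fit, "lorentzian_fit"))
  if (fit$flagged) stop("refusing to align with a flagged reference fit: ", fit$message)
  shift <- fit$centre
  if (abs(shift) > max_shift) {
    stop(sprintf("reference shift %.4f ppm exceeds the sanity bound %.4f ppm",
                 shift, max_shift))
  }
  y <- stats::approx(spec$axis, spec$intensities, xout = spec$axis + shift,
                     rule = 2)$y
  comps <- if (!is.null(spec$components)) {
    lapply(spec$components, function(cv) {
      stats::approx(spec$axis, cv, xout = spec$axis + shift, rule = 2)$y
    })
  }
  meta <- spec$meta; meta$aligned <- TRUE; meta$applied_shift <- -shift
  new_spectrum(spec$axis, y, components = comps, meta = meta)
}

#' Scale a spectrum by the reference (TSP) integral
#'
#' Multiplies intensities by `reference_fit$area / fit$area`, so the TSP
#' integral matches that of the reference spectrum (typically the
#' highest-scan-count acquisition of a series).
#'
#' @param spec A `spectrum`.
#' @param fit This spectrum's reference-peak fit.
#' @param reference_fit The reference spectrum's fit.
#' @return The scaled `spectrum` (`meta$scaling = "scaled"`).
#' @export
scale_by_reference <- function(spec, fit, reference_fit) {
  stopifnot(inherits(fit, "lorentzian_fit"), inherits(reference_fit, "lorentzian_fit"))
  if (!is.finite(fit$area) || fit$area <= 0) {
    stop("non-positive fitted reference area; cannot scale")
  }
  if (!is.finite(reference_fit$area) || reference_fit$area <= 0) {
    stop("non-positive reference area; cannot scale")
  }
  f <- reference_fit$area / fit$area
  meta <- spec$meta; meta$scaling <- "scaled"; meta$scale_factor <- f
  new_spectrum(spec$axis, spec$intensities * f,
               components = if (!is.null(spec$components)) {
                 lapply(spec$components, function(cv) cv * f)
               },
               meta = meta)
}

#' Align and scale a whole scan series
#'
#' Convenience pipeline mirroring standard processing: fit TSP in each
#' spectrum, align each to 0.00 ppm, and scale all to the last (highest scan
#' count) spectrum's TSP integral.
#'
#' @param series List of `spectrum` objects (e.g. from
#'   [acquisition_series()]).
#' @param window TSP fit window.
#' @return List with `spectra` (processed), `fits` (per-spectrum
#'   [fit_reference_peak()] results) and `skipped` (names of spectra left
#'   unscaled because their reference fit was flagged).
#' @export
preprocess_series <- function(series, window = ppm_interval(-0.05, 0.05)) {
  fits <- lapply(series, fit_reference_peak, window = window)
  ref_fit <- fits[[length(fits)]]
  skipped <- character(0)
  out <- vector("list", length(series)); names(out) <- names(series)
  for (i in seq_along(series)) {
    if (fits[[i]]$flagged) {
      skipped <- c(skipped, names(series)[i] %||% as.character(i))
      out[[i]] <- series[[i]]
      next
    }
    sp <- align_to_reference(series[[i]], fits[[i]])
    refit <- fit_reference_peak(sp, window)
    out[[i]] <- scale_by_reference(sp, if (refit$flagged) fits[[i]] else refit,
                                   ref_fit)
  }
  list(spectra = out, fits = fits, skipped = skipped)
}
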