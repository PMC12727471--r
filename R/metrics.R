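#' SNR conventions, metabolite bounds and detection thresholds
#'
#' Three signal-to-noise conventions are provided. The integral convention
#' defines SNR as the ratio of mean absolute intensities between a signal
#' region and a noise region:
#'   SNR = (sum_j |I(d_j)| / n) / (sum_i |I(d_i)| / m),
#' with n and m the point counts of the (closed) signal and noise intervals.
#' The two max-based conventions mirror the behaviour of common vendor
#' routines: signal is the maximum absolute intensity in the signal region,
#' noise is the RMS about the regional mean in the noise region, and the
#' "topspin-like" convention carries an extra factor of two in its noise
#' term, so vnmrj-like / topspin-like = 2 identically.
#'
#' The canonical noise region is [-2, -1] ppm, a signal-free stretch of
#' baseline upfield of TSP.
#'
#' @name metrics-module
NULL

#' A closed ppm interval
#' @param low,high Interval endpoints in ppm, `low < high`. Both endpoints are
#'   inclusive on the grid (fixes the point counts entering the SNR ratio).
#' @return Object of class `ppm_interval`.
#' @export
ppm_interval <- function(low, high) {
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    stop("require numeric low < high")
  }
  structure(list(low = low, high = high), class = "ppm_interval")
}

#' @export
print.ppm_interval <- function(x, ...) {
  cat(sprintf("<ppm_interval> [%.4f, %.4f] ppm\n", x$low, x$high))
  invisible(x)
}

#' Default noise region
#' @return `ppm_interval(-2, -1)`.
#' @export
noise_region <- function() ppm_interval(-2, -1)

#' Standard metabolite integration windows at 80 MHz
#'
#' The 2-sigma cumulative-intensity bounds for the bundled metabolites,
#' restricted for glucose and lactate to avoid the residual-water region:
#' glucose [3.19, 3.98] (excluding the anomeric protons between 4 and
#' 5.5 ppm), lactate [1.17, 1.50] (the methyl doublet only), citrate
#' [2.37, 2.82] ppm.
#' @return Named list of [ppm_interval()] objects.
#' @export
reference_bounds <- function() {
  list(glucose = ppm_interval(3.19, 3.98),
       lactate = ppm_interval(1.17, 1.50),
       citrate = ppm_interval(2.37, 2.82))
}

.snr_result <- function(value, method, signal_region, noise_region, n, m,
                        signal, noise) {
  structure(list(value = value, method = method,
                 signal_region = signal_region, noise_region = noise_region,
                 n_points_signal = n, n_points_noise = m,
                 signal = signal, noise = noise),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> %s: SNR = %.4g (signal [%.3f,%.3f], noise [%.3f,%.3f], n=%d, m=%d)\n",
              x$method, x$value, x$signal_region$low, x$signal_region$high,
              x$noise_region$low, x$noise_region$high,
              x$n_points_signal, x$n_points_noise))
  invisible(x)
}

.check_regions <- function(spec, signal_region, noise_region) {
  si <- .interval_idx(spec, signal_region)
  ni <- .interval_idx(spec, noise_region)
  if (length(si) == 0L) stop("signal region contains no axis points")
  if (length(ni) == 0L) stop("noise region contains no axis points")
  if (max(signal_region$low, noise_region$low) <
      min(signal_region$high, noise_region$high)) {
    stop("signal and noise regions must not overlap")
  }
  list(si = si, ni = ni)
}

#' Integral (mean-absolute-intensity) SNR
#'
#' @param spec A `spectrum`.
#' @param signal_region,noise_region [ppm_interval()]s; closed, non-overlapping.
#' @return An `snr_result` with `method = "integral"`.
#' @export
snr_integral <- function(spec, signal_region, noise_region = lfnmr::noise_region()) {
  idx <- .check_regions(spec, signal_region, noise_region)
  s <- mean(abs(spec$intensities[idx$si]))
  nz <- mean(abs(spec$intensities[idx$ni]))
  if (nz == 0) stop("noise region has zero mean absolute intensity (degenerate denominator)")
  .snr_result(s / nz, "integral", signal_region, noise_region,
              length(idx$si), length(idx$ni), s, nz)
}

#' Max-based SNR conventions
#'
#' @inheritParams snr_integral
#' @param convention `"vnmrj"` (signal / RMS noise) or `"topspin"`
#'   (signal / (2 x RMS noise)). Signal is max |I| over the signal region;
#'   noise is the RMS of mean-subtracted intensities over the noise region.
#' @return An `snr_result`.
#' @export
snr_max_based <- function(spec, signal_region,
                          noise_region = lfnmr::noise_region(),
                          convention = c("vnmrj", "topspin")) {
  convention <- match.arg(convention)
  idx <- .check_regions(spec, signal_region, noise_region)
  s <- max(abs(spec$intensities[idx$si]))
  y <- spec$intensities[idx$ni]
  rms <- sqrt(mean((y - mean(y))^2))
  if (rms == 0) stop("noise region has zero RMS (degenerate denominator)")
  denom <- if (convention == "topspin") 2 * rms else rms
  .snr_result(s / denom, paste0(convention, "_like"),
              signal_region, noise_region,
              length(idx$si), length(idx$ni), s, denom)
}

#' Cumulative-intensity metabolite bounds
#'
#' Integrates the (noiseless) simulated intensity from high to low ppm,
#' normalises the cumulative sum to one, and reports the ppm values at which
#' it crosses a quantile pair, plus the 0.5-crossing as the spectrum centre.
#' With the default 2-sigma pair (0.023, 0.977) the returned interval contains
#' about 95.4% of the total signal.
#'
#' @param sim A `spectrum` (noiseless simulation) or a component of one.
#' @param coverage `"2sigma"` (quantiles 0.023/0.977), `"1sigma"`
#'   (0.159/0.841), or a numeric quantile pair `(lower, upper)` with
#'   `0 < lower < upper < 1`.
#' @param restrict_to Optional [ppm_interval()]: only intensity inside it is
#'   considered (used e.g. to exclude anomeric or solvent regions).
#' @return List with `interval` ([ppm_interval()], low < high), `centre`
#'   (ppm at cumulative 0.5) and `quantile_pair`.
#' @export
compute_bounds <- function(sim, coverage = "2sigma", restrict_to = NULL) {
  qp <- if (is.character(coverage)) {
    switch(coverage,
           "2sigma" = c(0.023, 0.977),
           "1sigma" = c(0.159, 0.841),
           stop("coverage must be '1sigma', '2sigma' or a numeric pair"))
  } else as.numeric(coverage)
  if (length(qp) != 2L || qp[1] <= 0 || qp[2] >= 1 || qp[1] >= qp[2]) {
    stop("quantile pair must satisfy 0 < lower < upper < 1")
  }
  axis <- sim$axis; y <- sim$intensities
  if (!is.null(restrict_to)) {
    idx <- .interval_idx(sim, restrict_to)
    axis <- axis[idx]; y <- y[idx]
  }
  tot <- sum(y)
  if (tot <= 0) stop("total intensity must be positive for bounds computation")
  cum <- cumsum(y) / tot  # axis runs high -> low ppm
  # linear-interpolated crossing of the cumulative curve at level q; first
  # crossing in the integration direction breaks ties
  crossing <- function(q) {
    k <- which(cum >= q)[1]
    if (is.na(k)) return(axis[length(axis)])
    if (k == 1L) return(axis[1])
    f <- (q - cum[k - 1L]) / (cum[k] - cum[k - 1L])
    axis[k - 1L] + f * (axis[k] - axis[k - 1L])
  }
  upper <- crossing(qp[1])   # high-ppm edge (cumulative runs high->low)
  lower <- crossing(qp[2])
  centre <- crossing(0.5)
  list(interval = ppm_interval(min(lower, upper), max(lower, upper)),
       centre = centre, quantile_pair = qp)
}

#' Fraction of simulated intensity inside an interval
#'
#' @param sim A `spectrum`.
#' @param interval A [ppm_interval()].
#' @return Fraction in [0, 1] of the total intensity lying inside the closed
#'   interval.
#' @export
bounds_coverage <- function(sim, interval) {
  idx <- .interval_idx(sim, interval)
  sum(sim$intensities[idx]) / sum(sim$intensities)
}

#' Detection / quantification threshold crossings
#'
#' @param series Data frame with columns `n_scans` and `snr`, sorted by
#'   `n_scans` (or sortable; it is sorted internally).
#' @param thresholds Named numeric vector; defaults to the conventional
#'   limits of detection (SNR = 3) and quantification (SNR = 10).
#' @param power_law Optional [fit_power_law()] result; when supplied, a
#'   continuous crossing estimate `n = (threshold/A)^(1/B)` is also reported.
#' @return Data frame with one row per threshold: `threshold`, `n_scans`
#'   (smallest scan count with SNR >= threshold; NA if never reached),
#'   `reached`, and `n_interp` when a power-law fit is given.
#' @export
threshold_crossings <- function(series, thresholds = c(LOD = 3, LOQ = 10),
                                power_law = NULL) {
  if (NROW(series) == 0L) stop("series must be non-empty")
  series <- series[order(series$n_scans), , drop = FALSE]
  out <- data.frame(name = names(thresholds) %||% as.character(thresholds),
                    threshold = as.numeric(thresholds),
                    n_scans = NA_real_, reached = FALSE)
  for (i in seq_along(thresholds)) {
    k <- which(series$snr >= thresholds[i])[1]
    if (!is.na(k)) {
      out$n_scans[i] <- series$n_scans[k]
      out$reached[i] <- TRUE
    }
  }
  if (!is.null(power_law)) {
    out$n_interp <- (out$threshold / power_law$A)^(1 / power_law$B)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
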