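#' Signal ratios and power-law scan scaling
#'
#' The relative abundance of two metabolites is summarized by the ratio of
#' their summed intensities over their chemical-shift bounds,
#'   R_XY = S_X / S_Y = sum_j I_X(d_j) / sum_i I_Y(d_i).
#' Signed intensities are summed (not absolute values), so purely noisy
#' regions can legitimately yield near-zero or negative sums. Ratios can be
#' taken from raw spectra ("experimental-integration") or from fitted
#' template components ("simulation-fit").
#'
#' SNR growth with scan averaging is summarized by a power law
#' SNR = A * n_scans^B fitted by ordinary least squares in log-log space;
#' coherent averaging predicts B = 1/2. Because signal is linear in
#' concentration, rescaling the fitted amplitude A by a concentration factor
#' predicts the SNR series of a proportionally diluted sample.
#'
#' @name scaling-module
NULL

# Summed intensity over an interval plus first-order uncertainty:
# sd of a sum of k points with i.i.d. noise of RMS s is s * sqrt(k).
.region_sum <- function(axis, y, interval, noise_rms) {
  idx <- which(axis >= interval$low - 1e-12 & axis <= interval$high + 1e-12)
  list(sum = sum(y[idx]), k = length(idx), sd = noise_rms * sqrt(length(idx)))
}

#' Signal ratio between two metabolite regions
#'
#' @param x A `spectrum` (experimental-integration mode: raw intensities) or
#'   a [fit_mixture()] `composite_fit` (simulation-fit mode: fitted component
#'   intensities; `species` must name the numerator and denominator
#'   components).
#' @param bounds_X,bounds_Y [ppm_interval()]s for numerator and denominator.
#' @param species Length-2 character vector naming numerator and denominator
#'   species (required for `composite_fit` input; informational otherwise).
#' @param noise_region Region used to estimate the noise RMS entering the
#'   propagated uncertainty.
#' @return Object of class `ratio_result`: `value`, `uncertainty` (one
#'   sigma, first-order propagation), `source`, `S_X`, `S_Y`, `n_scans`.
#' @export
signal_ratio <- function(x, bounds_X, bounds_Y, species = c("X", "Y"),
                         noise_region = lfnmr::noise_region()) {
  if (inherits(x, "composite_fit")) {
    spec <- x$spectrum
    comp <- function(nm) {
      f <- x$fits[[nm]]
      if (is.null(f)) stop(sprintf("no fitted component for species '%s'", nm))
      f$component
    }
    yX <- comp(species[1]); yY <- comp(species[2])
    source <- "simulation-fit"
  } else if (inherits(x, "spectrum")) {
    spec <- x
    yX <- yY <- x$intensities
    source <- "experimental-integration"
  } else {
    stop("x must be a spectrum or a composite_fit")
  }
  ni <- .interval_idx(spec, noise_region)
  yn <- spec$intensities[ni]
  noise_rms <- sqrt(mean((yn - mean(yn))^2))
  sX <- .region_sum(spec$axis, yX, bounds_X, noise_rms)
  sY <- .region_sum(spec$axis, yY, bounds_Y, noise_rms)
  if (sY$sum == 0) stop("denominator region sum is zero")
  r <- sX$sum / sY$sum
  unc <- abs(r) * sqrt((sX$sd / sX$sum)^2 + (sY$sd / sY$sum)^2)
  structure(list(value = r, uncertainty = abs(unc), source = source,
                 species = species, S_X = sX$sum, S_Y = sY$sum,
                 n_scans = spec$meta$n_scans %||% NA_integer_),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> %s/%s = %.4g +/- %.2g (%s)\n",
              x$species[1], x$species[2], x$value, x$uncertainty, x$source))
  invisible(x)
}

#' Stability of signal ratios across a scan series
#'
#' For each source (experimental-integration / simulation-fit) reports the
#' standard deviation of the ratio across scan counts and the smallest scan
#' count from which all ratios stay within a relative tolerance of the
#' highest-scan-count reference ("fidelity onset").
#'
#' @param ratios List of [signal_ratio()] results (mixed sources allowed),
#'   each carrying its `n_scans`.
#' @param rel_tol Relative deviation from the max-scan reference regarded as
#'   retaining fidelity (default 0.2).
#' @return Data frame with one row per source: `source`, `sd`, `reference`
#'   (max-scan ratio), `fidelity_n` (NA when even the reference's neighbours
#'   deviate).
#' @export
ratio_stability <- function(ratios, rel_tol = 0.2) {
  df <- data.frame(
    source = vapply(ratios, `[[`, character(1), "source"),
    n_scans = vapply(ratios, function(r) as.numeric(r$n_scans), numeric(1)),
    value = vapply(ratios, `[[`, numeric(1), "value"))
  if (length(unique(df$n_scans)) < 3L) stop("need ratios at >= 3 scan counts")
  out <- do.call(rbind, lapply(split(df, df$source), function(d) {
    d <- d[order(d$n_scans), , drop = FALSE]
    ref <- d$value[nrow(d)]
    ok <- abs(d$value - ref) <= rel_tol * abs(ref)
    # smallest n such that every count from it upward stays within tolerance
    fid <- NA_real_
    for (i in seq_len(nrow(d))) {
      if (all(ok[i:nrow(d)])) { fid <- d$n_scans[i]; break }
    }
    data.frame(source = d$source[1], sd = stats::sd(d$value),
               reference = ref, fidelity_n = fid)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a power law SNR = A * n_scans^B
#'
#' Ordinary least squares of log(SNR) on log(n_scans); optionally restricted
#' to points with SNR above a floor (used to exclude noise-dominated points,
#' which bias the exponent low).
#'
#' @param series Data frame with columns `n_scans` and `snr` (all > 0 after
#'   flooring).
#' @param snr_floor Optional: drop points with `snr <= snr_floor`.
#' @return Object of class `power_law_fit`: `A`, `B`, `r_squared`,
#'   `n_used`, `scan_domain`.
#' @export
fit_power_law <- function(series, snr_floor = NULL) {
  d <- series
  if (!is.null(snr_floor)) d <- d[d$snr > snr_floor, , drop = FALSE]
  d <- d[d$snr > 0, , drop = FALSE]
  if (nrow(d) < 2L) stop("need at least 2 usable points for a power-law fit")
  m <- stats::lm(log(snr) ~ log(n_scans), data = d)
  # summary() warns on numerically perfect fits; R^2 is still well defined
  r2 <- suppressWarnings(summary(m)$r.squared)
  structure(list(A = unname(exp(stats::coef(m)[1])),
                 B = unname(stats::coef(m)[2]),
                 r_squared = r2,
                 n_used = nrow(d), scan_domain = range(d$n_scans),
                 snr_floor = snr_floor),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> SNR = %.4g * n^%.4g (R^2 = %.4f, %d points)\n",
              x$A, x$B, x$r_squared, x$n_used))
  invisible(x)
}

#' Predict a rescaled SNR series and score it against observations
#'
#' Predicts `SNR(n) = factor * A * n^B` — the expected series for a sample
#' diluted by `factor` — and, when an observed series is given, reports the
#' coefficient of determination and the maximum relative deviation.
#'
#' @param fit A [fit_power_law()] result.
#' @param factor Concentration rescaling factor (> 0), e.g. 1/2, 1/4, 1/8.
#' @param observed Optional data frame with `n_scans` and `snr`.
#' @return List with `predicted` (data frame `n_scans`, `snr`), and when
#'   observations are given, `r_squared` and `max_rel_dev`.
#' @export
rescale_prediction <- function(fit, factor, observed = NULL) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (factor <= 0) stop("factor must be positive")
  if (is.null(observed)) {
    n <- 2^(0:8)
    return(list(predicted = data.frame(n_scans = n,
                                       snr = factor * fit$A * n^fit$B)))
  }
  pred <- factor * fit$A * observed$n_scans^fit$B
  ss_res <- sum((observed$snr - pred)^2)
  ss_tot <- sum((observed$snr - mean(observed$snr))^2)
  list(predicted = data.frame(n_scans = observed$n_scans, snr = pred),
       r_squared = 1 - ss_res / ss_tot,
       max_rel_dev = max(abs(pred - observed$snr) / abs(observed$snr)))
}

#' SNR grid over concentrations and scan counts
#'
#' Regenerates heatmap-style SNR tables: for each concentration of a single
#' metabolite (plus TSP reference) and each scan count, the integral SNR over
#' the metabolite's bounds.
#'
#' @param species Metabolite name.
#' @param concentrations Vector of concentrations in mmol/L.
#' @param scan_list Scan counts (default 2^(0:8)).
#' @param profile A [pulse_profile()].
#' @param signal_region Bounds; defaults to [reference_bounds()].
#' @param config Base [acquisition_config()] (seed drives all noise).
#' @param ... Passed to [acquisition_series()].
#' @return Data frame with `concentration`, `n_scans`, `snr`, `total_time`.
#' @export
snr_grid <- function(species, concentrations, scan_list = 2^(0:8),
                     profile = pulse_profile("wet"),
                     signal_region = reference_bounds()[[species]],
                     config = acquisition_config(), ...) {
  if (is.null(signal_region)) stop("signal_region required for this species")
  rows <- list()
  for (ci in seq_along(concentrations)) {
    conc <- concentrations[ci]
    mix <- mixture_spec(stats::setNames(conc, species))
    cfg <- config
    cfg$seed <- as.integer((config$seed + 15485863 * ci) %% 2147483629)
    series <- acquisition_series(mix, profile, scan_list, cfg, ...)
    for (sp in series) {
      s <- snr_integral(sp, signal_region)
      rows[[length(rows) + 1L]] <- data.frame(
        concentration = conc, n_scans = sp$meta$n_scans,
        snr = s$value, total_time = sp$meta$total_time)
    }
  }
  do.call(rbind, rows)
}
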