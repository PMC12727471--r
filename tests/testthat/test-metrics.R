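flat_spec <- function(value_signal = 5, value_noise = 5) {
  axis <- ppm_axis(4, -2.2)
  y <- rep(value_noise, length(axis))
  y[axis >= 1 & axis <= 2] <- value_signal
  new_spectrum(axis, y)
}

test_that("equal constant intensity in both regions gives integral SNR 1", {
  sp <- flat_spec(5, 5)
  r <- snr_integral(sp, ppm_interval(1, 2))
  expect_equal(r$value, 1)
  expect_identical(r$method, "integral")
  expect_gt(r$n_points_signal, 0)
})

test_that("integral SNR is linear in signal-region intensity and invariant under global rescaling", {
  set.seed(2)
  axis <- ppm_axis(4, -2.2)
  y <- stats::rnorm(length(axis), 0, 1)
  y[axis >= 1 & axis <= 2] <- y[axis >= 1 & axis <= 2] + 20
  sp <- new_spectrum(axis, y)
  sig <- ppm_interval(1, 2)
  base <- snr_integral(sp, sig)$value
  y2 <- y; y2[axis >= 1 & axis <= 2] <- 3 * y2[axis >= 1 & axis <= 2]
  expect_equal(snr_integral(new_spectrum(axis, y2), sig)$value, 3 * base,
               tolerance = 1e-12)
  expect_equal(snr_integral(new_spectrum(axis, 7 * y), sig)$value, base,
               tolerance = 1e-12)
})

test_that("vnmrj-like over topspin-like SNR is exactly two on any spectrum", {
  set.seed(3)
  for (r in 1:5) {
    cfg <- acquisition_config(n_scans = 2^r, seed = 60 + r)
    sp <- simulate_acquisition(mixed_sample_spec(), pulse_profile("zg30"), cfg)
    for (region in reference_bounds()) {
      v <- snr_max_based(sp, region, convention = "vnmrj")$value
      t <- snr_max_based(sp, region, convention = "topspin")$value
      expect_identical(v / t, 2)
    }
  }
})

test_that("a single spike of height h over noise RMS sigma gives vnmrj-like h/sigma", {
  axis <- ppm_axis(4, -2.2)
  set.seed(4)
  y <- stats::rnorm(length(axis), 0, 2)
  y[which.min(abs(axis - 1.5))] <- 50
  sp <- new_spectrum(axis, y)
  nidx <- which(axis >= -2 & axis <= -1)
  rms <- sqrt(mean((y[nidx] - mean(y[nidx]))^2))
  expect_equal(snr_max_based(sp, ppm_interval(1.4, 1.6), convention = "vnmrj")$value,
               50 / rms, tolerance = 1e-12)
})

test_that("the three SNR conventions order as integral < topspin < vnmrj on the mixed sample", {
  for (n in c(4, 64, 256)) {
    cfg <- acquisition_config(n_scans = n, seed = 17, shift_jitter_sigma = 0)
    sp <- simulate_acquisition(mixed_sample_spec(), pulse_profile("zg30"), cfg)
    for (region in reference_bounds()) {
      i <- snr_integral(sp, region)$value
      t <- snr_max_based(sp, region, convention = "topspin")$value
      v <- snr_max_based(sp, region, convention = "vnmrj")$value
      expect_lt(i, t); expect_lt(t, v)
    }
  }
})

test_that("widening the signal region into baseline never increases integral SNR", {
  cfg <- acquisition_config(n_scans = 64, seed = 23, shift_jitter_sigma = 0)
  sp <- simulate_acquisition(mixture_spec(c(lactate = 2), water_scale = 0),
                             pulse_profile("zg30"), cfg)
  widths <- c(0, 0.1, 0.3, 0.6, 1.0)
  snrs <- vapply(widths, function(wd) {
    snr_integral(sp, ppm_interval(1.17 - wd, 1.50 + wd))$value
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})

test_that("cumulative bounds of a symmetric Lorentzian are centred on it", {
  axis <- ppm_axis(4, 0)
  d0 <- 2.0
  y <- 1 / (1 + ((axis - d0) / 0.01)^2)
  b <- compute_bounds(new_spectrum(axis, y))
  dx <- abs(mean(diff(axis)))
  expect_equal(b$centre, d0, tolerance = dx)
  expect_equal((b$interval$high - d0) - (d0 - b$interval$low), 0, tolerance = 2 * dx)
})

test_that("simulated citrate is centred near 2.6 ppm with ~95% 2-sigma coverage", {
  sim <- simulate_mixture(mixture_spec(c(citrate = 0.2),
                                       reference_concentration = 0))
  b <- compute_bounds(sim)
  expect_lt(abs(b$centre - 2.6), 0.05)
  cov <- bounds_coverage(sim, b$interval)
  expect_equal(cov, 0.954, tolerance = 0.01)
  # 1-sigma interval is nested inside and covers ~68%
  b1 <- compute_bounds(sim, coverage = "1sigma")
  expect_gt(b1$interval$low, b$interval$low)
  expect_lt(b1$interval$high, b$interval$high)
  expect_equal(bounds_coverage(sim, b1$interval), 0.682, tolerance = 0.01)
})

test_that("glucose 2-sigma bounds reproduce the published window", {
  sim <- simulate_mixture(mixture_spec(c(glucose = 10),
                                       reference_concentration = 0))
  # restricted below the anomeric/water region, as for the published bounds
  b <- compute_bounds(sim, restrict_to = ppm_interval(2.9, 4.0))
  expect_lt(abs(b$interval$low - 3.19), 0.08)
  expect_lt(abs(b$interval$high - 3.98), 0.08)
})

test_that("degenerate inputs to metrics raise informative errors", {
  sp <- flat_spec()
  expect_error(snr_integral(sp, ppm_interval(1, 2), ppm_interval(1.5, 2.5)),
               "overlap")
  expect_error(snr_integral(sp, ppm_interval(100, 101)), "no axis points")
  zero <- new_spectrum(ppm_axis(2, 0), rep(0, length(ppm_axis(2, 0))))
  expect_error(compute_bounds(zero), "positive")
  expect_error(ppm_interval(2, 1), "low < high")
})

test_that("threshold crossings report the first scan count at or above threshold", {
  series <- data.frame(n_scans = 2^(0:5), snr = c(1.2, 2.1, 3.4, 5.8, 9.7, 16))
  cr <- threshold_crossings(series)
  expect_equal(cr$n_scans[cr$name == "LOD"], 4)
  expect_equal(cr$n_scans[cr$name == "LOQ"], 32)
  expect_true(all(cr$reached))
  # never reached -> flagged
  low <- threshold_crossings(data.frame(n_scans = 2^(0:3), snr = rep(1.5, 4)))
  expect_false(any(low$reached))
  expect_true(all(is.na(low$n_scans)))
  expect_error(threshold_crossings(data.frame()), "non-empty")
  # power-law interpolation: exact for an exact power law
  pl <- fit_power_law(data.frame(n_scans = 2^(0:5), snr = 2 * sqrt(2^(0:5))))
  cr2 <- threshold_crossings(series, thresholds = c(X = 8), power_law = pl)
  expect_equal(cr2$n_interp, (8 / 2)^2, tolerance = 1e-6)
})
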