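test_that("a region ratioed against itself is one, and R_XY * R_YX = 1", {
  cfg <- acquisition_config(n_scans = 16, seed = 12, shift_jitter_sigma = 0)
  sp <- simulate_acquisition(mixed_sample_spec(), pulse_profile("zg30"), cfg)
  b <- reference_bounds()
  same <- signal_ratio(sp, b$lactate, b$lactate, c("lactate", "lactate"))
  expect_equal(same$value, 1, tolerance = 1e-12)
  xy <- signal_ratio(sp, b$lactate, b$glucose, c("lactate", "glucose"))
  yx <- signal_ratio(sp, b$glucose, b$lactate, c("glucose", "lactate"))
  expect_equal(xy$value * yx$value, 1, tolerance = 1e-12)
  expect_gte(xy$uncertainty, 0)
})

test_that("the noiseless mixture ratio matches the proton-count oracle", {
  sim <- simulate_mixture(mixed_sample_spec())
  b <- reference_bounds()
  r <- signal_ratio(sim, b$lactate, b$glucose, c("lactate", "glucose"))
  # proton stoichiometry: (3 CH3 protons x 2 mmol/L) / (6 ring protons x 10)
  expect_lt(abs(r$value - 0.100), 0.005)
  # and it equals the per-component in-bounds ratio to integration cross-talk
  lac <- sum(sim$components$lactate[sim$axis >= 1.17 & sim$axis <= 1.50])
  glu <- sum(sim$components$glucose[sim$axis >= 3.19 & sim$axis <= 3.98])
  expect_equal(r$value, lac / glu, tolerance = 0.02)
})

test_that("shrinking the citrate window reduces experimental ratio spread", {
  b <- reference_bounds()
  sim_cit <- simulate_mixture(mixture_spec(c(citrate = 0.2),
                                           reference_concentration = 0))
  narrow <- compute_bounds(sim_cit, coverage = c(0.0885, 0.9115))$interval  # ~1.35 sigma
  expect_lt(narrow$high - narrow$low, (b$citrate$high - b$citrate$low) / 2)
  ratios <- function(region) {
    vapply(1:12, function(s) {
      cfg <- acquisition_config(n_scans = 16, seed = 500 + s,
                                shift_jitter_sigma = 0)
      sp <- simulate_acquisition(mixed_sample_spec(), pulse_profile("zg30"), cfg)
      signal_ratio(sp, region, b$glucose, c("citrate", "glucose"))$value
    }, numeric(1))
  }
  expect_lt(stats::sd(ratios(narrow)), stats::sd(ratios(b$citrate)))
})

test_that("ratio stability summarises spread and fidelity onset per source", {
  mk <- function(vals, ns, source) {
    lapply(seq_along(vals), function(i) {
      structure(list(value = vals[i], uncertainty = 0, source = source,
                     species = c("x", "y"), n_scans = ns[i]),
                class = "ratio_result")
    })
  }
  ns <- c(1, 4, 16, 64)
  const <- mk(rep(0.1, 4), ns, "simulation-fit")
  drift <- mk(c(0.2, 0.13, 0.101, 0.1), ns, "experimental-integration")
  st <- ratio_stability(c(const, drift))
  expect_equal(st$sd[st$source == "simulation-fit"], 0)
  expect_equal(st$fidelity_n[st$source == "simulation-fit"], 1)
  # drift: 0.2 and 0.13 deviate by >20% from the 0.1 reference
  expect_equal(st$fidelity_n[st$source == "experimental-integration"], 16)
  expect_error(ratio_stability(mk(c(1, 2), c(1, 2), "s")), ">= 3")
})

test_that("an exact power law is fitted exactly", {
  d <- data.frame(n_scans = 2^(0:8), snr = 3 * sqrt(2^(0:8)))
  f <- fit_power_law(d)
  expect_equal(f$A, 3, tolerance = 1e-10)
  expect_equal(f$B, 0.5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_power_law(d[1, ]), "at least 2")
})

test_that("synthetic glucose scan series recover the square-root exponent", {
  b <- reference_bounds()
  Bs <- vapply(1:8, function(s) {
    ser <- acquisition_series(mixture_spec(c(glucose = 10)),
                              pulse_profile("wet"),
                              config = acquisition_config(seed = 800 + s,
                                                          shift_jitter_sigma = 0))
    d <- data.frame(
      n_scans = vapply(ser, function(x) as.numeric(x$meta$n_scans), numeric(1)),
      snr = vapply(ser, function(x) snr_integral(x, b$glucose)$value, numeric(1)))
    fit_power_law(d)$B
  }, numeric(1))
  expect_lt(abs(stats::median(Bs) - 0.5), 0.05)
})

test_that("an SNR floor raises the fitted exponent of a noise-dominated series", {
  # citrate-like conditions: weak signal, SNR ~ 1 at low scan counts
  b <- reference_bounds()
  deltas <- vapply(1:6, function(s) {
    ser <- acquisition_series(mixture_spec(c(citrate = 0.4)),
                              pulse_profile("wet"),
                              config = acquisition_config(seed = 900 + s,
                                                          shift_jitter_sigma = 0))
    d <- data.frame(
      n_scans = vapply(ser, function(x) as.numeric(x$meta$n_scans), numeric(1)),
      snr = vapply(ser, function(x) snr_integral(x, b$citrate)$value, numeric(1)))
    fit_power_law(d, snr_floor = 3)$B - fit_power_law(d)$B
  }, numeric(1))
  expect_gt(stats::median(deltas), 0)
})

test_that("rescaled power-law predictions track diluted concentration series", {
  b <- reference_bounds()
  cfg <- acquisition_config(seed = 321, shift_jitter_sigma = 0)
  series_for <- function(conc, seed_off) {
    c2 <- cfg; c2$seed <- cfg$seed + seed_off
    ser <- acquisition_series(mixture_spec(c(glucose = conc)),
                              pulse_profile("wet"), config = c2)
    data.frame(
      n_scans = vapply(ser, function(x) as.numeric(x$meta$n_scans), numeric(1)),
      snr = vapply(ser, function(x) snr_integral(x, b$glucose)$value, numeric(1)))
  }
  top <- series_for(10, 0)
  fit <- fit_power_law(top)
  # factor 1 reproduces the fit itself
  self <- rescale_prediction(fit, 1, top)
  expect_gt(self$r_squared, 0.95)
  for (fac in c(1 / 2, 1 / 4)) {
    obs <- series_for(10 * fac, 1000 * fac)
    refit <- fit_power_law(obs)
    expect_lt(abs(fac * fit$A - refit$A) / refit$A, 0.10)
    pred <- rescale_prediction(fit, fac, obs)
    expect_gt(pred$r_squared, 0.95)
  }
})
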