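test_that("noiseless parameters are recovered to 1e-4 relative", {
  axis <- ppm_axis(2, 0.5)
  tmpl <- metabolite_template("lactate")
  true <- c(A = 2.4, w = 1.3, xs = 0.004)
  y <- lfnmr:::.render_template(tmpl, axis, true["A"], true["w"], true["xs"])
  spec <- new_spectrum(axis, y, meta = list(spectrometer_freq = 80))
  f <- fit_template(spec, tmpl, reference_bounds()$lactate)
  expect_true(f$converged)
  expect_equal(f$A_rel, unname(true["A"]), tolerance = 1e-4)
  expect_equal(f$w, unname(true["w"]), tolerance = 1e-4)
  expect_lt(abs(f$x_s - true["xs"]), 1e-4 * true["w"] / 80)
})

test_that("fitted A_rel scales with the spectrum and x_s follows an axis shift", {
  axis <- ppm_axis(2, 0.5)
  tmpl <- metabolite_template("lactate")
  y <- lfnmr:::.render_template(tmpl, axis, 1.5, 1.0, 0)
  region <- reference_bounds()$lactate
  f1 <- fit_template(new_spectrum(axis, y), tmpl, region)
  f2 <- fit_template(new_spectrum(axis, 3 * y), tmpl, region)
  expect_equal(f2$A_rel, 3 * f1$A_rel, tolerance = 1e-6)
  expect_equal(f2$w, f1$w, tolerance = 1e-6)
  expect_lt(abs(f2$x_s - f1$x_s), 1e-8)
  # shift the data pattern by +0.01 ppm: fitted offset follows
  yshift <- stats::approx(axis, y, xout = axis - 0.01, rule = 2)$y
  f3 <- fit_template(new_spectrum(axis, yshift), tmpl, region)
  expect_lt(abs((f3$x_s - f1$x_s) - 0.01), 1e-5)
})

test_that("a noise-only region yields an effectively flat (near-baseline) fit", {
  # same acquisition with and without citrate: the citrate template fitted
  # where no citrate exists must come out far below the true-signal amplitude
  with_cit <- simulate_acquisition(
    mixed_sample_spec(), pulse_profile("zg30"),
    acquisition_config(n_scans = 256, seed = 31, shift_jitter_sigma = 0))
  no_cit <- simulate_acquisition(
    mixture_spec(c(glucose = 10, lactate = 2)), pulse_profile("zg30"),
    acquisition_config(n_scans = 256, seed = 31, shift_jitter_sigma = 0))
  region <- reference_bounds()$citrate
  f_sig <- fit_template(with_cit, "citrate", region)
  f_noise <- fit_template(no_cit, "citrate", region)
  expect_gte(f_noise$A_rel, 0)  # bound respected
  expect_lt(f_noise$A_rel, 0.25 * f_sig$A_rel)
})

test_that("glucose fits share one amplitude across the fixed 36:64 anomer pair", {
  sim <- simulate_mixture(mixed_sample_spec())
  f <- fit_template(sim, "glucose", reference_bounds()$glucose)
  expect_equal(f$A_rel, 10, tolerance = 0.02)
  expect_equal(f$w, 1, tolerance = 0.02)
  # the single fitted component reproduces both anomers' out-of-region
  # multiplets (anomeric doublets near 4.63 / 5.22 ppm)
  idx <- which(sim$axis >= 4.5 & sim$axis <= 5.4)
  expect_lt(max(abs(f$component[idx] - sim$components$glucose[idx])),
            0.05 * max(sim$components$glucose[idx]))
})

test_that("the composite mixture fit is the sum of components and self-consistent", {
  sim <- simulate_mixture(mixed_sample_spec())
  cf <- fit_mixture(sim, c("glucose", "lactate", "citrate"))
  expect_equal(cf$composite,
               Reduce(`+`, lapply(cf$fits, `[[`, "component")),
               tolerance = 1e-12)
  # independent per-region fits leave only sub-0.1% cross-talk residuals
  expect_lt(cf$residual_rmse, 1e-3 * max(sim$intensities))
  # out-of-region prediction: the lactate quartet near 4.1 ppm is recovered
  idx <- which(sim$axis >= 4.0 & sim$axis <= 4.25)
  expect_lt(max(abs(cf$fits$lactate$component[idx] - sim$components$lactate[idx])),
            0.05 * max(sim$components$lactate[idx]))
})

test_that("parameter-recovery error degrades monotonically with noise", {
  axis <- ppm_axis(2, 0.5)
  tmpl <- metabolite_template("lactate")
  y0 <- lfnmr:::.render_template(tmpl, axis, 2, 1, 0)
  region <- reference_bounds()$lactate
  err_at <- function(sigma) {
    errs <- vapply(1:9, function(r) {
      set.seed(700 + r)
      sp <- new_spectrum(axis, y0 + stats::rnorm(length(axis), 0, sigma))
      f <- fit_template(sp, tmpl, region)
      abs(f$A_rel - 2) / 2
    }, numeric(1))
    stats::median(errs)
  }
  errs <- vapply(c(0.1, 1, 10), err_at, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("template fit errors are raised for unusable regions", {
  sim <- simulate_mixture(mixture_spec(c(lactate = 2)))
  expect_error(fit_template(sim, "lactate", ppm_interval(1.33, 1.3315)),
               "more points than free parameters")
  expect_error(fit_mixture(sim, "tsp"), "no fit region")
})
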