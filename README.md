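# lfnmr

Detection-limit analysis for low-field (80 MHz) benchtop ¹H-NMR
metabolomics, without a spectrometer.

Benchtop NMR makes metabolite measurement cheap and cryogen-free, but at
80 MHz sensitivity is low and spectra are strongly second-order, so the
practical questions — *which blood metabolites are detectable at
physiological concentrations, in how many scans, under which pulse
sequence, and by which definition of signal-to-noise?* — are hard to answer
by inspection. `lfnmr` answers them on simulated data. It is aimed at
spectroscopists and metabolomics method developers who want to regenerate
and extend detection-limit benchmarks (LOD/LOQ scan counts, SNR scaling
laws, relative-quantification stability) for mixtures of glucose, lactate,
citrate and TSP, or for any metabolite whose spin system they can supply.

## What is inside

* **Spin-system simulator** — exact diagonalization of the isotropic
  Hamiltonian $H/h = \sum_i \nu_i I_{z,i} + \sum_{i<j} J_{ij}\,
  \mathbf{I}_i\!\cdot\!\mathbf{I}_j$ (full strong-coupling treatment, which
  low field demands), rendered as Lorentzian lines with area ∝ intensity ×
  concentration. Parameters for glucose (α/β anomers, 36:64), lactate,
  citrate and TSP are bundled.
* **Synthetic acquisition model** — scan averaging with white Gaussian
  noise (RMS ∝ $1/\sqrt{n_\text{scans}}$), `zg`/`zg30`/`wet` pulse-sequence
  profiles, a residual-water line ~200× the tallest metabolite peak, shift
  jitter, and the 6.1487 × 10⁻⁴ ppm digital grid of benchtop spectra. The
  default noise level is calibrated so the benchmark mixture gives glucose
  SNR ≈ 4.3 in a single `zg30` scan.
* **Metrics** — the integral SNR
  $\mathrm{SNR} = \overline{|I|}_\text{signal} / \overline{|I|}_\text{noise}$
  (noise window −2..−1 ppm), two max-based vendor-style conventions (their
  ratio is exactly 2), LOD (SNR = 3) / LOQ (SNR = 10) crossings, and
  cumulative-intensity metabolite bounds (1σ/2σ quantile windows).
* **Preprocessing** — TSP Lorentzian fitting, alignment to 0.00 ppm, and
  scaling by the TSP integral relative to a reference spectrum.
* **Template fitting** — per-metabolite simulated templates with three free
  parameters $(A_\text{rel} \ge 0, w, x_s)$, fitted by bounded nonlinear
  least squares inside each metabolite's window; composite mixture fits and
  fitted-versus-integrated signal ratios $R_{XY} = S_X / S_Y$.
* **Scan-scaling analysis** — power-law fits
  $\mathrm{SNR} = A\,n_\text{scans}^{B}$ in log–log space (theory:
  $B = 1/2$), SNR floors, and amplitude rescaling (1/2, 1/4, 1/8) to
  predict diluted-concentration series.
* **I/O and CLI** — CSV and JCAMP-DX readers/writers, a JSON spin-system
  library format, and a command-line interface (`inst/cli/lfnmr`) with
  `simulate | preprocess | snr | bounds | fit | ratio | powerlaw | heatmap`
  subcommands that wrap the exported functions.

## Worked example

Simulate the benchmark mixed sample (glucose 10 mmol/L, lactate 2 mmol/L,
citrate 0.2 mmol/L, TSP 100 µmol/L) over a 1–256 scan series and ask when
each metabolite becomes quantifiable:

```r
library(lfnmr)
mix <- mixed_sample_spec()
series <- acquisition_series(mix, pulse_profile("zg30"),
                             scan_list = 2^(0:8),
                             config = acquisition_config(seed = 42))
b <- reference_bounds()
snr <- data.frame(
  n_scans = as.integer(names(series)),
  glucose = sapply(series, function(s) snr_integral(s, b$glucose)$value),
  lactate = sapply(series, function(s) snr_integral(s, b$lactate)$value),
  citrate = sapply(series, function(s) snr_integral(s, b$citrate)$value))
round(snr, 2)
#>  n_scans glucose lactate citrate
#>        1    4.47    1.59    1.05
#>        2    6.15    1.91    1.02
#>        4    8.59    2.41    1.19
#>        8   11.70    2.97    1.24
#>       16   17.12    4.16    1.45
#>       32   23.49    5.40    1.82
#>       64   33.67    7.60    2.38
#>      128   45.71   10.13    3.17
#>      256   64.83   14.41    4.46
```

Glucose at 10 mmol/L rises from SNR 4.5 at one scan to 65 at 256; lactate
crosses LOD by 8–16 scans and LOQ near 128; citrate at 0.2 mmol/L only
clears LOD past 128 scans — the characteristic difficulty of sub-millimolar
metabolites at low field. Threshold crossings and the scan-scaling law for
glucose:

```r
glu <- data.frame(n_scans = snr$n_scans, snr = snr$glucose)
threshold_crossings(glu, power_law = fit_power_law(glu))
#>   name threshold n_scans reached  n_interp
#> 1  LOD         3       1    TRUE 0.4527466
#> 2  LOQ        10       8    TRUE 5.4351062
fit_power_law(glu)
#> <power_law_fit> SNR = 4.404 * n^0.4844 (R^2 = 0.9997, 9 points)
```

The fitted exponent 0.48 is the coherent-averaging square-root law. Relative
quantification and the simulation-derived integration windows:

```r
sim <- simulate_mixture(mix)   # noiseless 80 MHz spectrum
signal_ratio(sim, b$lactate, b$glucose, c("lactate", "glucose"))
#> <ratio_result> lactate/glucose = 0.102 +/- 3.3e-07 (experimental-integration)

cit <- simulate_mixture(mixture_spec(c(citrate = 0.2), reference_concentration = 0))
bd <- compute_bounds(cit)      # cumulative 2-sigma quantile bounds
#> citrate centre 2.60 ppm, 2-sigma bounds [2.38, 2.82], coverage 95.4%
```

The lactate/glucose ratio 0.102 matches the proton-count expectation
(3 × 2)/(6 × 10) = 0.100; the citrate window reproduces the standard
[2.37, 2.82] ppm bounds with ~95% signal coverage.

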