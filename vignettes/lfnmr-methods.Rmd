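---
title: "Simulating metabolite detection limits at low field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating metabolite detection limits at low field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfnmr)
```

`lfnmr` asks a practical question of benchtop (80 MHz) ^1^H-NMR metabolomics:
which blood metabolites, at physiological concentrations, produce a usable
signal in how many scans — and how much does the answer depend on how
signal-to-noise is defined and measured? Because access to spectrometer time
is the limiting resource, everything here runs on simulated spectra: a
quantum-mechanical spin-system simulator supplies noiseless metabolite
signatures, and a synthetic acquisition model turns them into realistic
multi-scan spectra on which the full detection-limit analysis
(SNR conventions, LOD/LOQ thresholds, integration bounds, template fitting,
scan-scaling laws) can be exercised end to end.

## The spin-system model

Each metabolite is a set of spin-1/2 protons with chemical shifts
$\delta_i$ (ppm) and scalar couplings $J_{ij}$ (Hz), evolving under the
standard isotropic liquid-state Hamiltonian (in frequency units)

$$ H/h \;=\; \sum_i \nu_i I_{z,i} \;+\; \sum_{i<j} J_{ij}\,
   \mathbf{I}_i \cdot \mathbf{I}_j, \qquad \nu_i = \delta_i f_0 , $$

with $f_0$ the spectrometer frequency in MHz. At 80 MHz many metabolites are
strongly coupled ($|\nu_i - \nu_j| \sim J_{ij}$), so first-order multiplet
rules fail; `compute_transitions()` therefore diagonalizes $H$ exactly. The
Hamiltonian is block diagonal in the total magnetization quantum number, so
each $m_z$ block is diagonalized separately and single-quantum transitions
are read off as squared matrix elements of the total lowering operator
between adjacent blocks. Intensities use the equal-population
(high-temperature) convention, normalized so that they sum to the number of
spins — one unit per observable proton, a sum that is exactly invariant
under the couplings and is verified against a structurally independent
dense-matrix implementation in the tests. Transitions below $10^{-8}$ of the
total intensity are pruned (configurable). The supported maximum is 12
spins ($2^{12}$-dimensional space); the largest bundled system is the
9-proton TSP singlet, and each glucose anomer has 7.

Spectra are rendered by `render_spectrum()` as sums of Lorentzians of a
common full width at half maximum (default 1.0 Hz), centred at each
transition with integrated area proportional to intensity × concentration
(mmol/L). The default linewidth is an effective value absorbing instrumental
broadening and the mild exponential apodization typical of benchtop
processing pipelines; it is a free parameter everywhere.

Spin-system parameters for glucose (α and β anomers, mixed at the
literature equilibrium 36:64), lactate, citrate and TSP ship as a JSON asset
with per-entry source identifiers. They follow GISSMO-style optimized spin
matrices cross-checked against HMDB shifts; since published library versions
differ in the third ppm decimal, reproductions of integration windows are
expected to agree to a few hundredths of a ppm, not exactly. Citrate is
modelled as two independent geminal AB pairs (Δδ = 0.14 ppm, J = −15.1 Hz):
at 80 MHz this is deep in the strong-coupling regime and produces the
characteristic roofed quartet centred near 2.6 ppm.

## The synthetic acquisition model

`simulate_acquisition()` emulates a benchtop measurement of a mixture:

* **Pulse profiles.** `zg` (90° pulse; signal 1.0/scan, 15 s/scan),
  `zg30` (30° pulse; signal $\sin 30^\circ = 0.5$/scan, 5 s/scan) and `wet`
  (solvent suppression; signal 0.95/scan, 5 s/scan, water attenuated
  $10^{-3}$, receiver gain ×4). These are phenomenological factors, not
  pulse-sequence physics: published durations and gains for specific
  instruments are not available, so the defaults encode the qualitative
  behaviour (zg strongest per scan, zg30 faster but weaker, wet trading a
  little signal for suppression and the higher gain it permits) and are all
  configurable.
* **Residual water.** A single Lorentzian at 4.8 ppm (default FWHM 3 Hz, the
  narrow residual HDO line of a predominantly deuterated buffer), with
  height `water_scale` (default 200) times the tallest metabolite peak —
  the dynamic-range regime of a deuterated-buffer mixture, where the
  anomeric glucose doublet near 4.7 ppm is obscured but the up-field windows
  are usable.
* **Noise.** Additive white Gaussian noise, i.i.d. per point per scan, in
  the frequency domain (the unitary image of time-domain white noise). The
  scan average of $n$ i.i.d. draws of sd $\sigma$ is itself Gaussian with sd
  $\sigma/\sqrt{n}$, so the average is drawn directly at that sd —
  distributionally identical to averaging $n$ per-scan draws and much
  cheaper. The default per-scan $\sigma = 12.85$ was fixed once by
  `calibrate_noise_sigma()`: it is the level at which the benchmark mixture
  (glucose 10, lactate 2, citrate 0.2 mmol/L, TSP 100 µmol/L) acquired with
  `zg30` at a single scan has glucose integral SNR ≈ 4.3, anchoring the
  whole synthetic noise scale to a realistic single-scan operating point.
* **Shift jitter.** A global chemical-shift offset drawn once per
  acquisition from N(0, 0.002 ppm), exercising the alignment stage.
* **Grid.** 6.1487 × 10⁻⁴ ppm point spacing (the digital resolution of
  80 MHz benchtop spectra), default range 10 to −2.2 ppm so the −2..−1 ppm
  noise window is always present.

All randomness flows from the configured seed; `acquisition_series()`
derives per-scan-count seeds deterministically and reuses one noiseless
render.

## Referencing: TSP fitting, alignment, scaling

`fit_reference_peak()` fits a single Lorentzian plus constant baseline
(there is no phase term — spectra are assumed phased) inside a window
around 0 ppm (default ±0.05 ppm). A fit that fails to converge, or whose
height does not rise credibly above the residual scatter, returns a
*flagged* result rather than an error: a poor reference fit is a property of
the data the caller must see, and at the default noise level the single-scan
TSP fit does fail this way, mirroring practice. `align_to_reference()`
shifts the axis so the fitted centre sits at 0.00 ppm (refusing shifts
beyond a 0.1 ppm sanity bound) and re-interpolates linearly onto the
canonical grid — the grid spacing is ~20× finer than a linewidth, so
higher-order interpolation would add nothing testable.
`scale_by_reference()` multiplies intensities by the ratio of reference to
observed TSP areas, making the fixed-concentration internal standard's
integral constant across a scan series.

## SNR conventions and detection thresholds

Three conventions are provided because reported detection limits depend
strongly on which one is used:

$$ \mathrm{SNR}_{\mathrm{int}}
  = \frac{\tfrac1n \sum_{j=1}^{n} |I(\delta_j)|}
         {\tfrac1m \sum_{i=1}^{m} |I(\delta_i)|} $$

over closed signal and noise windows (noise window −2..−1 ppm), and two
max-based conventions modelled on common vendor routines: signal =
max |I| in the signal window, noise = RMS about the regional mean, with the
"topspin-like" variant carrying an extra factor 2 in the noise term. The
exact forms of the commercial routines are not public in the sources this
package follows; the two reconstructed conventions satisfy the two
documented constraints (max-based signal; a factor-2 noise relationship), so
vnmrj-like/topspin-like = 2 holds identically, and on the synthetic mixed
sample the ordering integral < topspin-like < vnmrj-like holds for every
metabolite and scan count, because the broad integration windows include
substantial baseline. Conventional thresholds LOD = 3 and LOQ = 10 are
applied by `threshold_crossings()`, optionally interpolated through a
power-law fit.

## Cumulative-intensity bounds

`compute_bounds()` integrates the noiseless simulated intensity from high to
low ppm (the canonical display direction), normalizes the cumulative sum to
one, and reports the crossings of a quantile pair — (0.023, 0.977) for the
2σ window containing ≈95.4% of the signal, (0.159, 0.841) for 1σ — plus the
0.5-crossing as the spectrum centre. Crossings are linearly interpolated
between grid points; ties are broken at the first crossing in the
integration direction. For the bundled systems this reproduces the standard
windows used throughout (glucose [3.19, 3.98] restricted below the
anomeric/water region, lactate [1.17, 1.50] around the methyl doublet,
citrate [2.37, 2.82] with centre ≈ 2.6 ppm) to within a few hundredths of a
ppm, the spread expected from unprinted library versions and linewidths.

## Template fitting

A template is a metabolite's transition set rendered with three free
parameters: relative intensity $A_{\mathrm{rel}} \ge 0$, common linewidth
$w$ (Hz), and chemical-shift offset $x_s$ (ppm). Glucose is a single
template combining both anomers at the fixed 36:64 ratio (the ratio is
assumed, not fitted) under one shared amplitude, width and offset; one
offset per template is used throughout. Fitting is bounded trust-region
least squares (`minpack.lm`), restricted to the metabolite's window, with
$A_{\mathrm{rel}}$ bounded below at zero so that a window containing only
noise tends to a baseline fit rather than chasing negative excursions.
Initialization is cold-start (amplitude from the window maximum scaled by
the unit-template peak height, $w = 1$ Hz, $x_s = 0$) and converges from
there in the noiseless case to 10⁻⁴ relative or better.

The constant baseline inside the window is estimated as a jointly fitted
nuisance offset, not as the window median: in crowded windows such as the
glucose region the median is dominated by signal, and subtracting it biases
the fitted amplitude low by tens of percent even on noiseless data. The
median and no-baseline variants remain available (`baseline = "median"`,
`"none"`).

Per-species fits are independent; `fit_mixture()` sums the fitted
components into a composite. Because each window also contains tails of
*other* species (the lactate CH quartet at 4.1 ppm reaches into the glucose
window, for example), independent fits leave a small irreducible cross-talk
residual — about 7 × 10⁻⁴ of the maximum intensity on the noiseless
benchmark mixture — which is the self-consistency level the tests assert.
The fitted component is returned over the full axis, so multiplets outside
the fitting window (the lactate quartet, the anomeric glucose doublets) are
predictions of the fit, and on noiseless mixtures they agree with the true
components to a few percent.

## Signal ratios, stability, and scan scaling

`signal_ratio()` implements
$R_{XY} = \sum_j I_X(\delta_j) / \sum_i I_Y(\delta_i)$ over the species'
windows, from raw intensities ("experimental-integration") or fitted
components ("simulation-fit"). Signed intensities are summed deliberately:
noisy windows can legitimately integrate to near-zero or negative values,
which is part of what the comparison with template fitting is about. The
quoted one-sigma uncertainty uses a documented first-order rule — the sd of
a $k$-point sum of i.i.d. noise of RMS $s$ is $s\sqrt{k}$, with $s$
estimated from the noise window and propagated to the ratio; it is a
simple, testable convention rather than a full error model. On the
noiseless benchmark mixture the lactate/glucose ratio over the standard
windows is 0.102, matching the proton-count expectation
$(3 \times 2)/(6 \times 10) = 0.100$ to integration cross-talk.

`fit_power_law()` fits $\mathrm{SNR} = A\,n_{\mathrm{scans}}^{B}$ by
unweighted ordinary least squares in log–log space. Coherent averaging
predicts $B = 1/2$, and synthetic high-concentration glucose series recover
a median $B$ of 0.50 across noise seeds. For noise-dominated series
(citrate-like, SNR ≈ 1 at low scan counts) the unfloored exponent is biased
low because the integral SNR plateaus near 1; excluding points below an SNR
floor of 3 moves $B$ back toward 1/2 — the tests assert this direction of
effect. `rescale_prediction()` multiplies the fitted amplitude by a
concentration factor (1/2, 1/4, 1/8) to predict diluted series, which works
because signal is linear in concentration; on synthetic glucose series the
rescaled predictions match independently refitted amplitudes within 10%
down to quarter concentration.

## What the generator does and does not emulate

The acquisition model reproduces: thermal (white, Gaussian,
frequency-domain) noise and its $1/\sqrt{n}$ averaging; per-sequence signal
and gain factors; residual-water dynamic range; digital resolution; global
shift jitter. It deliberately omits structured experimental artifacts —
baseline distortion, phase errors, lineshape asymmetry, field drift within
a series — which are listed as non-goals of the design.

This has one important consequence for interpreting the test suite. With
purely white noise, direct signed integration over a metabolite window is
already an efficient, unbiased estimator of its summed signal, and the
measured experimental-integration ratio stability is an order of magnitude
better than what is observed on real instruments; meanwhile the template
fit pays a variance penalty for its nuisance parameters (width–amplitude
anticorrelation) and, at SNR ≈ 1, an $A_{\mathrm{rel}} \ge 0$ censoring
bias. The real-data advantage of simulation-based fitting — greater ratio
stability at low scan counts — arises from exactly the structured artifacts
the generator omits (the measured sensitivity of the integrated ratio to
the one structured effect we do model, residual misalignment, is below
3 × 10⁻⁵ per 0.002 ppm). The corresponding ensemble comparison in the
acceptance tests is therefore expected to fail under this generator, and is
kept failing rather than weakened: passing it here would say nothing about
real data, and its failure is a quantitative statement about which noise
structures the fitting advantage actually requires.

## Numerical choices and problem sizes

Degenerate inputs error early and informatively: empty or overlapping
SNR regions, zero-intensity bounds input, non-positive reference areas,
fit windows smaller than the parameter count, spin systems beyond the
12-spin cap. Quantile and centre crossings interpolate linearly with
first-crossing tie-breaks. Optimizer tolerances are 10⁻⁸–10⁻¹⁰ relative
with at most 300 iterations; non-convergence flags the result instead of
erroring.

The test and acceptance workloads use the full 19,842-point canonical grid,
scan series of 2⁰–2⁸, and ensembles of 6–20 noise seeds (10 for the
stability comparison); these sizes give stable medians for every stochastic
quantity asserted while keeping a complete run in the low minutes on one
core. The power-law acceptance benchmark uses 20 seeds × 9 scan counts;
its median exponent is stable to ±0.01 across base seeds.

## Known limitations

* No relaxation (T1/T2), NOE, time-domain FID effects, or pH/temperature
  shift prediction; linewidth is a single effective parameter.
* Pulse-profile factors are phenomenological, not derived from sequence
  physics; per-scan durations are plausible placeholders.
* The commercial SNR routines are reconstructed "-like" conventions, not
  bit-compatible reimplementations.
* Bundled spin parameters are literature values; third-decimal ppm
  differences from any particular library release propagate to bounds and
  centres at the 0.01–0.06 ppm level.
* The white-noise generator understates real experimental instability of
  integrated ratios, as discussed above.
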