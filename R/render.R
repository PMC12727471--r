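#' Lorentzian rendering of transition lists and mixtures
#'
#' Transitions are rendered as Lorentzian lines of a common full width at half
#' maximum, centred at each transition's ppm position, with integrated area
#' proportional to (transition intensity) x (concentration). The effective
#' linewidth absorbs instrumental broadening and any exponential apodization
#' applied during processing.
#'
#' @name render-module
NULL

# Sum of Lorentzians evaluated on a ppm grid.
# positions/areas in ppm / (intensity*ppm); fwhm in ppm.
.lorentz_sum <- function(axis, positions, areas, fwhm_ppm) {
  hw <- fwhm_ppm / 2
  out <- numeric(length(axis))
  for (i in seq_along(positions)) {
    out <- out + (areas[i] / pi) * hw / ((axis - positions[i])^2 + hw^2)
  }
  out
}

#' Render a transition list as a Lorentzian spectrum
#'
#' @param transitions A `transition_list` from [compute_transitions()].
#' @param axis ppm grid (see [ppm_axis()]).
#' @param linewidth Full width at half maximum of each line, in Hz.
#' @param concentration Species concentration in mmol/L; line areas scale
#'   linearly with it (area units: one unit per proton per mmol/L).
#' @param spectrometer_freq Spectrometer frequency in MHz (converts Hz to
#'   ppm); defaults to the frequency stored on the transition list.
#' @param axis_shift Global ppm offset added to all line positions (used for
#'   chemical-shift jitter).
#' @return A `spectrum` whose single component is named after the system.
#' @export
render_spectrum <- function(transitions, axis, linewidth = 1,
                            concentration = 1, spectrometer_freq = NULL,
                            axis_shift = 0) {
  stopifnot(inherits(transitions, "transition_list"))
  if (linewidth <= 0) stop("linewidth must be positive (Hz FWHM)")
  if (is.null(spectrometer_freq)) {
    spectrometer_freq <- attr(transitions, "spectrometer_freq")
  }
  pos <- transitions$frequency_hz / spectrometer_freq + axis_shift
  if (any(pos > max(axis) | pos < min(axis))) {
    warning("axis does not cover all transitions; tails truncated")
  }
  areas <- transitions$intensity * concentration
  y <- .lorentz_sum(axis, pos, areas, linewidth / spectrometer_freq)
  new_spectrum(axis, y,
               meta = list(spectrometer_freq = spectrometer_freq,
                           linewidth_hz = linewidth,
                           concentration = concentration))
}

#' Specify a metabolite mixture
#'
#' @param species Named numeric vector or list of concentrations in mmol/L,
#'   e.g. `c(glucose = 10, lactate = 2, citrate = 0.2)`. The name `glucose`
#'   expands to the alpha and beta anomer spin systems at their equilibrium
#'   36:64 populations.
#' @param reference_concentration TSP concentration in mmol/L (default 0.1,
#'   i.e. 100 umol/L); set to 0 to omit the reference.
#' @param water_ppm Position of the residual water resonance (default 4.8).
#' @param water_scale Residual-water peak height as a multiple of the tallest
#'   metabolite peak (default 200, the regime of a predominantly deuterated
#'   solvent); applies only to synthetic acquisitions.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(species, reference_concentration = 0.1,
                         water_ppm = 4.8, water_scale = 200) {
  species <- unlist(species)
  if (is.null(names(species)) || any(!nzchar(names(species)))) {
    stop("species must be a named vector of concentrations (mmol/L)")
  }
  if (any(species < 0)) stop("concentrations must be >= 0")
  if (reference_concentration < 0) stop("reference_concentration must be >= 0")
  structure(list(species = species,
                 reference_concentration = reference_concentration,
                 water_ppm = water_ppm, water_scale = water_scale),
            class = "mixture_spec")
}

#' The benchmark mixed sample
#'
#' Glucose 10 mmol/L, lactate 2 mmol/L, citrate 0.2 mmol/L with 100 umol/L
#' TSP: the standard mixture used throughout for detection-limit benchmarks.
#' @inheritParams mixture_spec
#' @return A [mixture_spec()].
#' @export
mixed_sample_spec <- function(water_scale = 200) {
  mixture_spec(c(glucose = 10, lactate = 2, citrate = 0.2),
               reference_concentration = 0.1, water_scale = water_scale)
}

#' Simulate a noiseless mixture spectrum
#'
#' Renders each species (glucose expanded into its anomers, sharing the
#' mixture concentration via the 36:64 populations), plus the TSP reference
#' when `reference_concentration > 0`, and sums them. Component vectors are
#' retained per mixture species so fitted/simulated signal ratios can be taken
#' per metabolite.
#'
#' @param mixture A [mixture_spec()].
#' @param axis ppm grid.
#' @param linewidth Hz FWHM for all lines (default 1).
#' @param spectrometer_freq MHz (default 80).
#' @param library Metabolite library from [load_metabolite_library()];
#'   defaults to the bundled one.
#' @param axis_shift Global ppm offset (jitter) applied to all species.
#' @return A `spectrum` with per-species `components`.
#' @export
simulate_mixture <- function(mixture, axis = ppm_axis(), linewidth = 1,
                             spectrometer_freq = 80,
                             library = default_library(),
                             axis_shift = 0) {
  stopifnot(inherits(mixture, "mixture_spec"))
  conc <- mixture$species
  if (mixture$reference_concentration > 0 && !"tsp" %in% names(conc)) {
    conc <- c(conc, tsp = mixture$reference_concentration)
  }
  comps <- vector("list", length(conc)); names(comps) <- names(conc)
  for (nm in names(conc)) {
    systems <- resolve_species(library, nm)
    y <- numeric(length(axis))
    for (sys in systems) {
      tr <- .transitions_cached(sys, spectrometer_freq)
      y <- y + render_spectrum(tr, axis, linewidth,
                               concentration = conc[[nm]] * sys$population,
                               spectrometer_freq = spectrometer_freq,
                               axis_shift = axis_shift)$intensities
    }
    comps[[nm]] <- y
  }
  total <- Reduce(`+`, comps, numeric(length(axis)))
  new_spectrum(axis, total, components = comps,
               meta = list(spectrometer_freq = spectrometer_freq,
                           linewidth_hz = linewidth, scaling = "unscaled",
                           mixture = mixture))
}

# Per-session cache of diagonalizations keyed by system name + frequency;
# the bundled systems are small but re-rendered many times in scan series.
.transition_cache <- new.env(parent = emptyenv())
.transitions_cached <- function(system, spectrometer_freq) {
  key <- paste0(system$name, "@", format(spectrometer_freq, digits = 12), "#",
                paste(format(c(system$shifts, system$couplings), digits = 12),
                      collapse = ","))
  if (is.null(.transition_cache[[key]])) {
    .transition_cache[[key]] <- compute_transitions(system, spectrometer_freq)
  }
  .transition_cache[[key]]
}
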