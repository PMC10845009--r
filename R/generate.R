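# Synthetic data generators. Generators communicate with the analysis
# modules only through plain pattern/spectrum objects, never by passing
# schedule values directly, so recovery tests stay honest.

# q positions of the allowed reflections for a phase at lattice parameter a.
phase_peak_positions <- function(phase, a) {
  rule <- saxs_rules(phase)[[1]]
  switch(rule$geometry,
         cubic = 2 * pi * rule$spacing_ratios / a,
         hexagonal = 4 * pi * rule$spacing_ratios / (sqrt(3) * a),
         lamellar = 2 * pi * rule$spacing_ratios / a)
}

#' Generate a SAXS temperature series from a scenario
#'
#' Per temperature, sums Lorentzian Bragg peaks at the allowed reflections
#' of the scheduled phase(s) - during coexistence both peak sets appear
#' with amplitudes crossfaded across the transition window - on a
#' power-law background, with multiplicative Gaussian noise.
#'
#' @param scenario a [mesophase_scenario()].
#' @param temperatures deg C grid (defaults to the scenario's SAXS grid).
#' @param q scattering-vector grid in nm^-1.
#' @param noise relative noise amplitude (defaults to the scenario's).
#' @param seed RNG seed (defaults to the scenario's).
#' @param peak_hwhm Lorentzian half width at half maximum in nm^-1.
#' @return A list of [saxs_pattern()] objects.
#' @export
gen_saxs_series <- function(scenario, temperatures = scenario$temperatures$saxs,
                            q = seq(0.3, 3, by = 0.002),
                            noise = scenario$noise$saxs,
                            seed = scenario$seed, peak_hwhm = 0.01) {
  stopifnot(inherits(scenario, "mesophase_scenario"))
  with_seed(seed, lapply(temperatures, function(Tc) {
    ph <- scheduled_phase(scenario, Tc)
    frac <- c(Pn3m = 1 - ph$hex_fraction, HII = ph$hex_fraction)
    intensity <- 5 * q^-1.5 + 1  # diffuse background
    for (phase in ph$phases) {
      qhkl <- phase_peak_positions(phase, scheduled_lattice(scenario, Tc,
                                                            phase = phase))
      amps <- 100 * seq_along(qhkl)^-0.8 * frac[[phase]]
      for (j in seq_along(qhkl))
        intensity <- intensity +
          amps[j] * peak_hwhm^2 / ((q - qhkl[j])^2 + peak_hwhm^2)
    }
    intensity <- intensity * (1 + stats::rnorm(length(q), 0, noise))
    saxs_pattern(q, pmax(intensity, 0), temperature = Tc,
                 water_wt = scenario$water_wt)
  }))
}

#' Generate a lattice-parameter hydration series from a scenario
#'
#' Evaluates the cubic-phase swelling law of the scenario at one
#' temperature over a composition grid (lattice parameter grows with water
#' content up to the excess-water boundary, then plateaus) and adds
#' multiplicative noise. This emulates the per-composition lattice
#' parameters an experimenter would extract from patterns at increasing
#' hydration.
#'
#' @param scenario a [mesophase_scenario()].
#' @param temperature deg C.
#' @param water_wt composition grid in wt%.
#' @param noise relative noise on the lattice parameter.
#' @param seed RNG seed.
#' @return A data frame with `water_wt` and `a_nm`.
#' @export
gen_lattice_series <- function(scenario, temperature = 30,
                               water_wt = seq(25, 50, by = 2.5),
                               noise = 0.003, seed = scenario$seed) {
  stopifnot(inherits(scenario, "mesophase_scenario"))
  a <- vapply(water_wt, function(wt)
    scheduled_lattice(scenario, temperature, water_wt = wt, phase = "Pn3m"),
    numeric(1))
  with_seed(seed, {
    a <- a * (1 + stats::rnorm(length(a), 0, noise))
  })
  data.frame(water_wt = water_wt, a_nm = a)
}

#' Generate a dielectric temperature series from a scenario
#'
#' Per temperature, evaluates the scheduled Havriliak-Negami model (three
#' processes plus dc conductivity) on a log-spaced frequency grid covering
#' 1e-2 to 1e6 Hz and adds independent relative Gaussian noise to the real
#' and imaginary parts.
#'
#' @param scenario a [mesophase_scenario()].
#' @param temperatures deg C grid (defaults to the scenario's BDS grid).
#' @param frequency Hz grid.
#' @param noise relative noise amplitude.
#' @param seed RNG seed.
#' @return A list of `"dielectric_spectrum"` objects.
#' @export
gen_bds_series <- function(scenario, temperatures = scenario$temperatures$bds,
                           frequency = 10^seq(-2, 6, length.out = 113),
                           noise = scenario$noise$bds, seed = scenario$seed) {
  stopifnot(inherits(scenario, "mesophase_scenario"))
  with_seed(seed, lapply(temperatures, function(Tc) {
    sp <- evaluate_model(scheduled_model(scenario, Tc), frequency,
                         temperature = Tc, water_wt = scenario$water_wt)
    n <- length(frequency)
    sp$eps_real <- sp$eps_real * (1 + stats::rnorm(n, 0, noise))
    sp$eps_imag <- pmax(sp$eps_imag * (1 + stats::rnorm(n, 0, noise)), 0)
    sp
  }))
}

#' Generate an FTIR temperature series from a scenario
#'
#' Per temperature, sums Gaussian components at the scheduled centres,
#' widths and amplitudes over 1000-3800 cm^-1 (headgroup Sn bands, the
#' carbonyl doublet, CH stretches, and the three OH-stretch water
#' components), adds a linear baseline and multiplicative noise.
#'
#' @param scenario a [mesophase_scenario()].
#' @param temperatures deg C grid (defaults to the scenario's FTIR grid).
#' @param wavenumber cm^-1 grid (default 2 cm^-1 resolution).
#' @param noise relative noise amplitude.
#' @param seed RNG seed.
#' @return A list of [ftir_spectrum()] objects.
#' @export
gen_ftir_series <- function(scenario, temperatures = scenario$temperatures$ftir,
                            wavenumber = seq(1000, 3800, by = 2),
                            noise = scenario$noise$ftir,
                            seed = scenario$seed) {
  stopifnot(inherits(scenario, "mesophase_scenario"))
  bl <- scenario$ftir$baseline
  with_seed(seed, lapply(temperatures, function(Tc) {
    bands <- scheduled_bands(scenario, Tc)
    absorb <- bl[1] + bl[2] * (wavenumber - 1000)
    for (j in seq_len(nrow(bands)))
      absorb <- absorb + bands$amplitude[j] *
        exp(-0.5 * ((wavenumber - bands$center[j]) / bands$width[j])^2)
    absorb <- absorb * (1 + stats::rnorm(length(wavenumber), 0, noise))
    ftir_spectrum(wavenumber, absorb, temperature = Tc,
                  water_wt = scenario$water_wt)
  }))
}
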