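# mesokit

Multi-modal analysis of lyotropic lipidic mesophases across the
cubic-to-reverse-hexagonal phase transition, with and without excess
water.

Lipidic mesophases such as the monolinolein–water system self-assemble
into a diamond bicontinuous cubic phase (Pn3m) at moderate temperature
and a reverse hexagonal phase (HII) at high temperature. Beyond a
swelling limit (~40 wt% water at 30 °C) additional water stays outside
the structure as *excess water* and plasticises the lipid dynamics.
mesokit implements the three measurement analyses such a study rests on,
for scientists working with scattering and spectroscopy data from
lipid/surfactant mesophases:

* **SAXS** (`detect_peaks`, `index_phase`, `fit_lattice_parameter`,
  `detect_excess_water_boundary`, `build_phase_diagram`): Bragg-peak
  detection, phase assignment from spacing-ratio rules
  (Pn3m √2:√3:√4:√6:√8:√9, HII 1:√3:√4, Ia3d, Im3m, lamellar), lattice
  parameters from q = 2π·√(h²+k²+l²)/a (cubic) or
  q = 4π·√(h²+hk+k²)/(√3·a) (hexagonal), coexistence windows, and the
  excess-water boundary from the lattice-parameter plateau versus
  hydration.
* **Broadband dielectric spectroscopy** (`evaluate_model`,
  `fit_spectrum`, `build_relaxation_map`, `detect_kink`): sums of
  Havriliak–Negami processes plus dc conductivity,
  ε\*(ω) = ε∞ + Σₖ Δεₖ/(1 + (iωτₖ)^αₖ)^γₖ with ε″ ← ε″ + σ/(ωε₀),
  fitted in the ε″ or tan δ representation; relaxation times at maximum
  loss via τ_max = τ_HN·[sin(παγ/(2+2γ))/sin(πα/(2+2γ))]^(1/α);
  Arrhenius relaxation maps with continuation fitting and
  piecewise-linear kink detection at the phase transition.
* **FTIR** (`fit_band`, `water_fractions`, `carbonyl_ratio`,
  `band_center_trend`): Gaussian sub-band deconvolution of the
  headgroup, ester-carbonyl (H-bonded 1725 / free 1736 cm⁻¹),
  CH-stretch and OH-stretch regions; hydrogen-bond water populations
  Φₓ = Aₓ/A_tot from the 3300/3450/3600 cm⁻¹ OH components; carbonyl
  free:H-bonded intensity ratio; band-centre temperature trends with
  discontinuity detection.
* **Synthetic data** (`scenario_m70w30`, `scenario_m55w45`,
  `gen_saxs_series`, `gen_bds_series`, `gen_ftir_series`,
  `gen_lattice_series`, `write_scenario_tree`): seeded generators that
  emulate the 70/30 and 55/45 lipid/water samples from declarative
  ground-truth schedules, for validation and method development.
* **Pipeline** (`run_study`, `compare_excess_water`,
  `write_study_report`): orchestration over one sample's three series,
  cross-modality transition consensus, and the with/without-excess-water
  comparison. A thin CLI lives at `inst/scripts/mesokit.R`.

## Worked example

```r
library(mesokit)

sc <- scenario_m70w30()                      # 30 wt% water, no excess water

# SAXS: phase bands and the coexistence window
patterns <- gen_saxs_series(sc, seed = 7)
diagram  <- build_phase_diagram(patterns)
coexistence_window(diagram)
#> [1] 50 62

# Dielectric: relaxation map of three lipid processes, kink at the transition
spectra <- gen_bds_series(sc, seed = 2)
map <- build_relaxation_map(spectra, n_processes = 3, seed = 1)
max(map$data$tau_max_s[map$data$process == 1])
#> [1] 100.4084
detect_kink(map, process = 1)$kink_temperature
#> [1] 55

# FTIR: water populations at 30 degrees C
spec <- gen_ftir_series(sc, temperatures = 30, seed = 6)[[1]]
water_fractions(fit_band(spec, "oh_stretch", seed = 6))$phi
#> OH_strong   OH_less   OH_weak
#> 0.4591418 0.3997637 0.1410945
```

The coexistence window 50–62 °C is where the cubic and hexagonal Bragg
families are both present; the slowest dielectric process reaches
~100 s at the cold end of the series and its Arrhenius branch changes
slope at 55 °C, inside that window; and at 30 °C about 46% of the water
is strongly (tetrahedrally) hydrogen-bonded, 40% is in distorted
coordination and 14% only weakly bound.

## Layout

```
R/                 saxs, bds, ftir, scenario/generate, io, pipeline, breakpoint
tests/testthat/    unit, property and end-to-end tests (independent oracles
                   in helper-oracles.R)
scripts/           acceptance.R
inst/scripts/      mesokit.R command-line wrapper
vignettes/         methods vignette (models, parameters, design choices)
```
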