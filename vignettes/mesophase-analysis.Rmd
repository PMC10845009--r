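---
title: "Methods: multi-modal analysis of lipidic mesophases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal analysis of lipidic mesophases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesokit)
```

mesokit analyses lyotropic lipidic mesophases — here the
monolinolein–water system — across the thermotropic transition from the
double-diamond bicontinuous cubic phase (Pn3m) to the reverse hexagonal
phase (HII), comparing samples below the swelling limit (≈30 wt% water)
and in equilibrium with excess water (≈45 wt%). Three modalities are
implemented end to end: SAXS phase indexing, broadband dielectric
relaxation analysis, and FTIR band deconvolution. A synthetic-data module
generates internally consistent series from declarative scenarios so that
every estimator can be validated against known ground truth.

## SAXS: phase indexing and the phase diagram

A 1-D powder pattern of a lyotropic phase shows Bragg reflections whose
positions, relative to the first allowed reflection, follow fixed
spacing-ratio sequences: √2:√3:√4:√6:√8:√9 for Pn3m, 1:√3:√4 for HII,
√6:√8:√14:√16:√20:√22 for Ia3d. `detect_peaks()` smooths the pattern with
a 5-point centred moving average, keeps local maxima whose topographic
prominence exceeds a fraction (default 2%) of the maximum intensity, and
refines positions by 3-point parabolic interpolation on the
log-intensity (a Lorentzian or Gaussian peak is locally parabolic in log
space, so the refinement is unbiased at the grid scale).

`index_phase()` scores each candidate rule by the number of observed
positions matching its ratio sequence within a relative tolerance
(default 1.5%, the largest value at which the supported full rule sets
remain mutually exclusive). Ties are broken first toward the rule whose
matched reflections form the more contiguous low-order sequence, then by
residual: this matters because the complete HII triplet 1:√3:2 is also,
numerically, the √2:√6:√8 subset of Pn3m with three reflections missing —
an assignment a crystallographer would reject for exactly this reason.
Two-phase coexistence is handled greedily: the winning rule claims its
peaks, the leftovers are re-indexed against the remaining rules, and
coexistence is reported when the second rule matches at least two
leftover peaks. The exhaustive search over rule pairs, anchors and
partitions is kept as a test oracle only; the greedy result agrees with
it on the scenarios generated here, and the phase boundaries in the
coexistence region are inherently approximate anyway because the two
reflection families overlap.

Lattice parameters come from a least-squares slope through the origin of
peak position against the reflection modulus m (m = √(h²+k²+l²) for
cubic, √(h²+hk+k²) for hexagonal): a = 2π/slope (cubic) or
4π/(√3·slope) (hexagonal). Indexing is therefore exactly scale
invariant, and multiplying all positions by c divides a by c.

Beyond the swelling limit, added water no longer enters the mesophase
and the lattice parameter plateaus. `detect_excess_water_boundary()`
fits a continuous increase-then-plateau model (plateau slope fixed at
zero, breakpoint scanned over the composition grid) and accepts the
plateau only when it beats a single straight line by BIC, spans at least
two points, and the rising limb has positive slope.

## Dielectric relaxation: Havriliak–Negami fitting and the kink

The complex permittivity is modelled as a sum of Havriliak–Negami (HN)
processes plus a dc-conductivity loss term:

ε*(ω) = ε∞ + Σₖ Δεₖ / (1 + (iωτₖ)^αₖ)^γₖ,  ε″ ← ε″ + σ/(ωε₀),

with 0 < α, αγ ≤ 1 (α = γ = 1 is Debye). The principal branch of the
complex power is used; tests cross-check it against the textbook polar
decomposition. The relaxation time at maximum loss follows the closed
form τ_max = τ_HN·[sin(παγ/(2+2γ))/sin(πα/(2+2γ))]^(1/α), which the test
suite verifies against dense grid search over an (α, γ) lattice to
better than 0.1%. In the loss-tangent representation (tan δ = ε″/ε′) a
Debye peak shifts up in frequency by the factor √(1 + Δε/ε_h); the
closed form and a brute-force maximisation agree in the tests.

`fit_spectrum()` minimises relative residuals of the chosen
representation (tan δ by default, matching how such spectra are usually
reported; ε″ available) with Levenberg–Marquardt under box constraints,
parameters in log space for Δε, τ and σ. Note that tan δ is invariant
under a common scaling of ε∞, all Δεₖ and σ, so the loss-tangent fit
determines strengths only up to that scale — the relaxation times,
which carry the physics here, are unaffected.

Initialisation is data-driven rather than random: candidate relaxation
times are taken from prominence-filtered local maxima of the smoothed
log-loss *and* of the log-loss-tangent (a slow process whose ε″ peak has
drifted below the measurement window can still peak inside it in tan δ),
merged, clustered to a quarter decade, and combined into structural
variants; relaxation strengths are initialised from the dispersion steps
of ε′ between neighbouring peaks. Each variant is polished with restarts
until the residual stops improving, randomized perturbations add
robustness, and the lowest-residual solution wins. Peak detection runs
on the raw loss, not a conductivity-subtracted one: the monotone σ/ω
rise cannot create local maxima, whereas subtracting an estimated
conductivity produces cancellation artifacts at the low-frequency edge.

`build_relaxation_map()` fits a temperature series by continuation: the
anchor temperature — chosen automatically as the series end with more
resolvable loss peaks — is fitted with the full multi-start search, and
each neighbouring temperature starts from the previous solution with a
mild quadratic tether (weight 2 by default) on the slowly-varying
parameters (Δε, α, γ, ε∞, σ; never τ). The tether addresses a real
identifiability limit: once a process's loss peak leaves the window only
the flank is measured, and on a flank Δε/τ trades off against σ almost
freely. Carrying the strength information from temperatures where the
peak was in-window resolves the degeneracy the way an experienced
spectroscopist would — by demanding continuity in temperature — and
recovers the slowest process at the cold end of the study grid to a few
percent where isolated fits err by 25% or more.

Phase-transition kinks are detected in Arrhenius coordinates
(log₁₀ τ_max versus 1/T): `detect_breakpoint()` scans a continuous
two-segment linear model over the interior grid points and reports the
breakpoint only when it beats a single line by BIC (penalising the hinge
with two extra parameters, the second slope and the scanned breakpoint).
The same routine, unchanged, performs the FTIR trend-discontinuity test,
so the two modalities apply one criterion.

## FTIR: band deconvolution and water populations

Four regions are predefined with their assignment centres: the lipid
headgroup window 1000–1230 cm⁻¹ (Sn3, Sn2, and the ester CO–O–C stretch
Sn1 at 1180 cm⁻¹), the ester carbonyl window 1680–1780 cm⁻¹ with the
H-bonded (1725 cm⁻¹) and free (1736 cm⁻¹) sub-components, the CH-stretch
window (CH₂ symmetric 2856, antisymmetric 2924, methylene CH ≈3010
cm⁻¹), and the OH-stretch window 3100–3700 cm⁻¹ with the strongly
(≈3300), less strongly (≈3450) and weakly (≈3600 cm⁻¹) hydrogen-bonded
water components.

`fit_band()` performs box-constrained least squares of a sum of
Gaussians plus a linear baseline over the region window. Centres may
move from their assignment values by at most max(5 cm⁻¹, 20% of the
component width); widths are, by default, held at the assignment values
("tethered" mode). That choice is deliberate: a seeded simulation sweep
showed that with free widths the three-component OH deconvolution at
0.5% multiplicative noise wanders ±0.09 in the population fractions and
±10 cm⁻¹ in the centre along a near-degenerate trade-off direction, even
though noiseless recovery is exact — the envelope simply does not
constrain eleven free shape parameters. With widths tethered, recovery
is better than 0.01 in the fractions and 0.5 cm⁻¹ in the centres. A
`width_mode = "free"` escape hatch (bounded to ±20–25%) exists for data
whose widths genuinely differ from the defaults, with the caveat above.

Water populations are Φₓ = Aₓ/A_tot over the three OH components; they
sum to one by construction. The carbonyl balance is reported as the
free:H-bonded intensity (amplitude) ratio, with the area ratio
alongside; with tethered equal widths the two coincide.

## The synthetic-data scenarios

The two presets encode the study conditions as declarative schedules:

* Temperature grids per modality: SAXS 30–66 °C every 4 °C, dielectric
  31–70 °C every 3 °C, FTIR 28–70 °C every 3 °C.
* Phase schedule: Pn3m below 50 °C, coexistence 50–62 °C, HII above.
  Coexistence crossfades the two Bragg-peak families linearly over
  mixing fractions 0.2–0.8 (not 0–1) so both phases remain detectable at
  the window edges. Bragg peaks are Lorentzians (HWHM 0.01 nm⁻¹) with
  amplitudes ∝ j^-0.8 on a q^-1.5 background, 1% multiplicative noise.
* Lattice schedule: the cubic lattice parameter grows with hydration at
  0.08 nm per wt% from 9.0 nm at (30 °C, 25 wt%) up to the swelling
  limit — 40 wt% at 30 °C, drifting to lower hydration by 0.15 wt%/°C —
  and shrinks with temperature at 0.02 nm/°C; the hexagonal branch is
  analogous around 6.4 nm.
* Relaxation schedule: three HN processes whose log₁₀ τ_max is
  piecewise-linear in 1/T with a slope change at 55 °C. The slowest
  process spans 100 → 0.1 s (M70-W30) and 0.1 → 0.001 s (M55-W45); the
  intermediate process slows again in the HII phase in both samples;
  the fastest process slows in HII for M70-W30 but accelerates slightly
  for M55-W45. Every M55-W45 branch lies below its M70-W30 counterpart
  at every temperature (the plasticizer effect of excess water).
  Strengths, ε∞ and σ (Δε = 30/6/3 and 35/7/3.5, ε∞ = 2.5/3.0,
  σ = 1/5 pS/m) are order-of-magnitude choices, not literature values;
  σ is kept small enough that the conductivity loss does not swamp the
  slowest process at the window edge, as appropriate for a weakly
  conductive lipid matrix. Noise is 0.5% relative on ε′ and ε″.
* FTIR schedule: Gaussian components at the assignment centres with
  temperature trends — CH₂ stretches blue-shift by ~1 cm⁻¹ across
  30→66 °C; the methylene CH red-shifts by 2 cm⁻¹ across the transition
  in M70-W30 only; Sn bands red-shift with a marked slope change at
  55 °C; the OH populations drift linearly in M55-W45 but break at
  55 °C in M70-W30; the carbonyl intensity ratio rises with temperature
  in M70-W30 and falls in M55-W45. Sn2/Sn3 centres (1120/1060 cm⁻¹) and
  all widths are package choices within the stated windows. Noise is
  0.5% multiplicative.

The phase window, the relaxation kink and the FTIR discontinuity are
mutually consistent by construction (all inside 50–62 °C, kink at
55 °C), which is what lets `run_study()` test cross-modality consensus
meaningfully. Generators hand the analysis modules only plain
pattern/spectrum objects, never schedule values, so recovery tests stay
honest.

What the generators deliberately do not emulate: instrumental resolution
smearing and form-factor modulation in SAXS, electrode polarisation in
the dielectric spectra (the low-frequency rise is attributed to σ only),
Mie/scattering baselines and water-vapour lines in FTIR, and any
non-Gaussian band shape. Passing the recovery tests therefore
demonstrates the estimators' correctness and conditioning, not
robustness to every artifact of real instruments.

## Numerical choices and degenerate inputs

* All nonlinear fits use `minpack.lm::nls.lm` (Levenberg–Marquardt with
  box constraints) on parameters log-transformed where positive.
* Relative residuals are used for both modalities, matching the
  multiplicative noise model and weighting the log-spaced grids
  uniformly per point.
* BIC is computed as n·log(SSE/n) + k·log(n) with an SSE floor of
  10⁻¹² · Σy² shared by both models, so noiseless inputs fall back to
  the parameter penalty and a pure line is never split.
* Empty or constant SAXS patterns yield an empty peak set, not an
  error; single-peak sets raise an "ambiguous" condition; a grid point
  that cannot be indexed is labelled and skipped, never fatal.
* Breakpoints are reported at grid points (no sub-step interpolation):
  with 3–4 °C steps, sub-step precision would overstate what the data
  support.

## Study-level orchestration

`run_study()` runs the three stages independently (failures are caught
and reported per stage), derives a transition interval per modality —
the SAXS coexistence window, the slowest-process kink ±1 temperature
step, the OH-population discontinuity ±1 step — and intersects them; an
empty intersection is flagged as disagreement rather than resolved.
`compare_excess_water()` forms per-process ratios of relaxation times at
common temperatures and compares FTIR trend directions, which is how the
plasticizer effect (ratios ≥ 10 for the slowest process) and the
opposite carbonyl behaviour of the two samples are quantified.

Problem sizes used throughout the tests and the acceptance script are
the study grids themselves (10 SAXS temperatures, 14 dielectric
temperatures, 15 FTIR temperatures, 11 hydration points); the full
three-modality analysis of both samples runs in seconds.

## Known limitations

* The greedy two-phase indexer can mis-partition when more than two
  phases coexist or when lattice parameters conspire to overlap
  reflection families within tolerance; the exhaustive oracle exists in
  the test suite but is exponential and not exported.
* Loss-tangent fitting cannot determine the absolute Δε scale (see
  above); use the ε″ representation when strengths matter.
* A relaxation process whose peak never enters the measured window at
  any temperature of the series is unrecoverable by continuation; the
  map will report its flank-degenerate estimate flagged by residual
  inspection rather than refuse.
* JCAMP-DX support covers AFFN-encoded XYDATA/XYPOINTS blocks only (no
  SQZ/DIF compression).
* Voigt or Lorentzian band shapes are not implemented; all FTIR
  sub-bands are Gaussian.
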