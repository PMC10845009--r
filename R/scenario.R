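# Declarative ground-truth scenarios for synthetic data generation.
# A scenario fixes, per temperature: the mesophase(s) present, the lattice
# parameters, the dielectric model (three HN processes with per-phase
# Arrhenius branches kinked at the transition, plus conductivity), and the
# FTIR component schedules (centres, widths, areas, water-population
# fractions, carbonyl ratio direction).

#' Construct a ground-truth mesophase scenario
#'
#' The returned object carries every schedule the three generators need:
#' phase/transition window, lattice-parameter swelling law with the
#' excess-water plateau, per-process relaxation-time Arrhenius branches
#' (nodes interpolated linearly in inverse absolute temperature), and FTIR
#' band-centre / area schedules. Use the presets [scenario_m70w30()] and
#' [scenario_m55w45()] for the two study compositions: 30 wt% water (no
#' excess water) and 45 wt% water (mesophase in equilibrium with excess
#' water).
#'
#' @param name scenario label.
#' @param water_wt water content in wt%.
#' @param transition_window `c(lo, hi)` deg C over which the cubic and
#'   reverse hexagonal phases coexist (default 50-62).
#' @param kink_temperature deg C where relaxation and band schedules change
#'   slope (default 55, inside the window).
#' @param lattice named list of swelling-law constants (see source).
#' @param hn named list: `nodes` (per process, matrix of (T deg C,
#'   log10 tau_max s)), `delta_eps`, `alpha`, `gamma`, `eps_inf`, `sigma`.
#' @param ftir named list of band schedules (see source).
#' @param noise per-modality relative noise amplitudes.
#' @param temperatures per-modality default temperature grids.
#' @param seed default RNG seed for the generators.
#' @return An object of class `"mesophase_scenario"`.
#' @export
mesophase_scenario <- function(name, water_wt, transition_window = c(50, 62),
                               kink_temperature = 55,
                               lattice, hn, ftir,
                               noise = list(saxs = 0.01, bds = 0.005,
                                            ftir = 0.005),
                               temperatures = list(saxs = seq(30, 66, by = 4),
                                                   bds = seq(31, 70, by = 3),
                                                   ftir = seq(28, 70, by = 3)),
                               seed = 1L) {
  stopifnot(transition_window[1] < transition_window[2],
            kink_temperature >= transition_window[1],
            kink_temperature <= transition_window[2])
  phis <- vapply(c(temperatures$ftir, 30, 66), function(Tc)
    sum(scheduled_phi_raw(ftir, Tc)), numeric(1))
  stopifnot(all(abs(phis - 1) < 1e-9))
  structure(list(name = name, water_wt = water_wt,
                 transition_window = transition_window,
                 kink_temperature = kink_temperature,
                 lattice = lattice, hn = hn, ftir = ftir,
                 noise = noise, temperatures = temperatures, seed = seed),
            class = "mesophase_scenario")
}

#' @export
print.mesophase_scenario <- function(x, ...) {
  cat(sprintf("scenario %s: %g wt%% water, transition %g-%g C, seed %d\n",
              x$name, x$water_wt, x$transition_window[1],
              x$transition_window[2], x$seed))
  invisible(x)
}

#' @rdname mesophase_scenario
#' @param seed RNG seed stored on the preset.
#' @export
scenario_m70w30 <- function(seed = 7L) {
  mesophase_scenario(
    name = "M70-W30", water_wt = 30, seed = seed,
    lattice = list(
      a0_cubic = 9.0, swell_cubic = 0.08, slope_cubic = 0.02, T0_cubic = 30,
      a0_hex = 6.4, swell_hex = 0.03, slope_hex = 0.01, T0_hex = 50,
      wt_ref = 25, boundary_wt0 = 40, boundary_T0 = 30, boundary_slope = 0.15),
    hn = list(
      nodes = list(
        rbind(c(31, 2.0), c(55, -0.3), c(70, -1.0)),   # process 1, 0.1-100 s
        rbind(c(31, -3.0), c(55, -4.0), c(70, -3.5)),  # process 2, slows in HII
        rbind(c(31, -6.0), c(55, -6.7), c(70, -6.4))), # process 3
      delta_eps = c(30, 6, 3), alpha = c(1, 0.9, 0.8), gamma = c(1, 1, 0.7),
      eps_inf = 2.5, sigma = 1e-12),
    ftir = list(
      # centre schedules: piecewise-linear nodes (T deg C, cm^-1)
      centers = list(
        Sn3 = rbind(c(28, 1060.0), c(55, 1059.2), c(70, 1056.2)),
        Sn2 = rbind(c(28, 1120.0), c(55, 1119.2), c(70, 1116.5)),
        Sn1 = rbind(c(28, 1180.0), c(55, 1179.2), c(70, 1176.9)),
        CO_bonded = rbind(c(28, 1725.2), c(70, 1724.4)),
        CO_free = rbind(c(28, 1736.2), c(70, 1735.4)),
        CH2_sym = rbind(c(30, 2856.0), c(66, 2857.0)),
        CH2_asym = rbind(c(30, 2924.0), c(66, 2925.0)),
        CH_methylene = rbind(c(28, 3010.0), c(52, 3010.0), c(62, 3008.0),
                             c(70, 3008.0)),
        OH_strong = rbind(c(28, 3300), c(70, 3300)),
        OH_less = rbind(c(28, 3450), c(70, 3450)),
        OH_weak = rbind(c(28, 3600), c(70, 3600))),
      widths = c(Sn3 = 12, Sn2 = 13, Sn1 = 14, CO_bonded = 8, CO_free = 8,
                 CH2_sym = 9, CH2_asym = 11, CH_methylene = 12,
                 OH_strong = 90, OH_less = 85, OH_weak = 60),
      amplitudes = c(Sn3 = 0.22, Sn2 = 0.25, Sn1 = 0.30, CH2_sym = 0.55,
                     CH2_asym = 0.75, CH_methylene = 0.22),
      # water populations: marked slope change at 55 C (no excess water)
      phi_strong = rbind(c(28, 0.460), c(55, 0.4276), c(70, 0.3526)),
      phi_less = rbind(c(28, 0.400), c(55, 0.4216), c(70, 0.4861)),
      oh_total_area = 60,
      carbonyl_total_amplitude = 0.85,
      # free : H-bonded intensity ratio rises with T (free CO increases)
      carbonyl_ratio = rbind(c(28, 0.85), c(70, 1.27)),
      baseline = c(0.01, 5e-6)),
    noise = list(saxs = 0.01, bds = 0.005, ftir = 0.005))
}

#' @rdname mesophase_scenario
#' @export
scenario_m55w45 <- function(seed = 7L) {
  mesophase_scenario(
    name = "M55-W45", water_wt = 45, seed = seed,
    lattice = list(
      a0_cubic = 9.0, swell_cubic = 0.08, slope_cubic = 0.02, T0_cubic = 30,
      a0_hex = 6.4, swell_hex = 0.03, slope_hex = 0.01, T0_hex = 50,
      wt_ref = 25, boundary_wt0 = 40, boundary_T0 = 30, boundary_slope = 0.15),
    hn = list(
      nodes = list(
        rbind(c(31, -1.0), c(55, -2.5), c(70, -3.0)),    # 0.001-0.1 s
        rbind(c(31, -4.0), c(55, -4.6), c(70, -4.5)),
        rbind(c(31, -6.35), c(55, -6.78), c(70, -6.85))), # slightly faster in HII
      delta_eps = c(35, 7, 3.5), alpha = c(1, 0.9, 0.8), gamma = c(1, 1, 0.7),
      eps_inf = 3.0, sigma = 5e-12),
    ftir = list(
      centers = list(
        Sn3 = rbind(c(28, 1060.5), c(55, 1059.9), c(70, 1057.2)),
        Sn2 = rbind(c(28, 1120.5), c(55, 1119.9), c(70, 1117.5)),
        Sn1 = rbind(c(28, 1180.5), c(55, 1179.9), c(70, 1178.0)),
        CO_bonded = rbind(c(28, 1724.8), c(70, 1725.6)),
        CO_free = rbind(c(28, 1735.8), c(70, 1736.6)),
        CH2_sym = rbind(c(30, 2856.2), c(66, 2856.9)),
        CH2_asym = rbind(c(30, 2924.2), c(66, 2924.9)),
        CH_methylene = rbind(c(28, 3010.0), c(70, 3009.5)),
        OH_strong = rbind(c(28, 3300), c(70, 3300)),
        OH_less = rbind(c(28, 3450), c(70, 3450)),
        OH_weak = rbind(c(28, 3600), c(70, 3600))),
      widths = c(Sn3 = 12, Sn2 = 13, Sn1 = 14, CO_bonded = 8, CO_free = 8,
                 CH2_sym = 9, CH2_asym = 11, CH_methylene = 12,
                 OH_strong = 90, OH_less = 85, OH_weak = 60),
      amplitudes = c(Sn3 = 0.18, Sn2 = 0.21, Sn1 = 0.25, CH2_sym = 0.45,
                     CH2_asym = 0.62, CH_methylene = 0.18),
      # bulk-like excess water: linear trends, no discontinuity
      phi_strong = rbind(c(28, 0.480), c(70, 0.396)),
      phi_less = rbind(c(28, 0.395), c(70, 0.4496)),
      oh_total_area = 80,
      carbonyl_total_amplitude = 0.70,
      # excess water H-bonds the interface: ratio falls with T
      carbonyl_ratio = rbind(c(28, 1.10), c(70, 0.848)),
      baseline = c(0.01, 5e-6)),
    noise = list(saxs = 0.01, bds = 0.005, ftir = 0.005))
}

# --- schedule evaluators --------------------------------------------------

#' Evaluate scenario schedules at given temperatures
#'
#' `scheduled_phase` returns the programmed phase label(s) and the reverse
#' hexagonal mixing fraction (the coexistence window maps linearly onto
#' fractions 0.2-0.8 so both phases stay detectable at the window edges).
#' `scheduled_lattice` returns the lattice parameter (nm) of one phase at a
#' (temperature, composition) point, honouring the excess-water plateau.
#' `excess_boundary_wt` returns the maximum water content the mesophase
#' accommodates at a temperature. `scheduled_tau_max` returns the
#' programmed per-process relaxation times, `scheduled_model` the full
#' dielectric model (converting tau_max to tau_HN with the HN peak-shift
#' factor), `scheduled_bands` the FTIR component table, `scheduled_phi`
#' the water-population fractions, and `scheduled_carbonyl_ratio` the
#' free:H-bonded intensity ratio.
#'
#' @param scenario a [mesophase_scenario()].
#' @param temperature deg C (scalar).
#' @return See details per function.
#' @export
scheduled_phase <- function(scenario, temperature) {
  w <- scenario$transition_window
  if (temperature < w[1]) {
    list(phases = "Pn3m", hex_fraction = 0)
  } else if (temperature > w[2]) {
    list(phases = "HII", hex_fraction = 1)
  } else {
    f <- 0.2 + 0.6 * (temperature - w[1]) / (w[2] - w[1])
    list(phases = c("Pn3m", "HII"), hex_fraction = f)
  }
}

#' @rdname scheduled_phase
#' @export
excess_boundary_wt <- function(scenario, temperature) {
  L <- scenario$lattice
  L$boundary_wt0 - L$boundary_slope * (temperature - L$boundary_T0)
}

#' @rdname scheduled_phase
#' @param water_wt composition in wt% (defaults to the scenario's).
#' @param phase `"Pn3m"` or `"HII"`.
#' @export
scheduled_lattice <- function(scenario, temperature,
                              water_wt = scenario$water_wt,
                              phase = c("Pn3m", "HII")) {
  phase <- match.arg(phase)
  L <- scenario$lattice
  wt_eff <- pmin(water_wt, excess_boundary_wt(scenario, temperature))
  if (phase == "Pn3m") {
    L$a0_cubic + L$swell_cubic * (wt_eff - L$wt_ref) -
      L$slope_cubic * (temperature - L$T0_cubic)
  } else {
    L$a0_hex + L$swell_hex * (wt_eff - L$wt_ref) -
      L$slope_hex * (temperature - L$T0_hex)
  }
}

#' @rdname scheduled_phase
#' @export
scheduled_tau_max <- function(scenario, temperature) {
  vapply(scenario$hn$nodes, function(nd)
    10^interp_inv_kelvin(nd, temperature), numeric(1))
}

#' @rdname scheduled_phase
#' @export
scheduled_model <- function(scenario, temperature) {
  h <- scenario$hn
  tmx <- scheduled_tau_max(scenario, temperature)
  procs <- lapply(seq_along(tmx), function(k)
    hn_process(h$delta_eps[k],
               tmx[k] / hn_peak_shift(h$alpha[k], h$gamma[k]),
               h$alpha[k], h$gamma[k]))
  dielectric_model(procs, eps_inf = h$eps_inf, sigma = h$sigma)
}

# phi vector (strong, less, weak) from the raw ftir schedule list.
scheduled_phi_raw <- function(ftir, temperature) {
  s <- interp_linear(ftir$phi_strong, temperature)
  l <- interp_linear(ftir$phi_less, temperature)
  c(OH_strong = s, OH_less = l, OH_weak = 1 - s - l)
}

#' @rdname scheduled_phase
#' @export
scheduled_phi <- function(scenario, temperature) {
  scheduled_phi_raw(scenario$ftir, temperature)
}

#' @rdname scheduled_phase
#' @export
scheduled_carbonyl_ratio <- function(scenario, temperature) {
  interp_linear(scenario$ftir$carbonyl_ratio, temperature)
}

#' @rdname scheduled_phase
#' @export
scheduled_bands <- function(scenario, temperature) {
  ft <- scenario$ftir
  labels <- names(ft$centers)
  centers <- vapply(labels, function(lb)
    interp_linear(ft$centers[[lb]], temperature), numeric(1))
  widths <- ft$widths[labels]
  amps <- stats::setNames(rep(NA_real_, length(labels)), labels)
  fixed <- intersect(names(ft$amplitudes), labels)
  amps[fixed] <- ft$amplitudes[fixed]
  # carbonyl doublet from the scheduled intensity ratio
  r <- scheduled_carbonyl_ratio(scenario, temperature)
  amps["CO_bonded"] <- ft$carbonyl_total_amplitude / (1 + r)
  amps["CO_free"] <- ft$carbonyl_total_amplitude * r / (1 + r)
  # OH components from the scheduled populations and total area
  phi <- scheduled_phi_raw(ft, temperature)
  for (lb in names(phi))
    amps[lb] <- phi[[lb]] * ft$oh_total_area / (widths[lb] * sqrt(2 * pi))
  data.frame(label = labels, center = unname(centers),
             width = unname(widths), amplitude = unname(amps),
             stringsAsFactors = FALSE)
}
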