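test_that("all three generators are deterministic under a fixed seed", {
  sc <- scenario_m70w30()
  expect_identical(gen_saxs_series(sc, temperatures = c(30, 54), seed = 7),
                   gen_saxs_series(sc, temperatures = c(30, 54), seed = 7))
  expect_identical(gen_bds_series(sc, temperatures = c(31, 55), seed = 2),
                   gen_bds_series(sc, temperatures = c(31, 55), seed = 2))
  expect_identical(gen_ftir_series(sc, temperatures = c(28, 55), seed = 6),
                   gen_ftir_series(sc, temperatures = c(28, 55), seed = 6))
  # and they do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_saxs_series(sc, temperatures = 30, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("generated patterns carry the published reflection ratios", {
  sc <- scenario_m70w30()
  cold <- gen_saxs_series(sc, temperatures = 30, seed = 7)[[1]]
  pk <- detect_peaks(cold)
  expect_gte(length(pk$positions), 6L)
  top6 <- pk$positions[order(pk$prominences, decreasing = TRUE)[1:6]]
  ratios <- sort(top6) / min(top6)
  expect_true(all(abs(ratios / (sqrt(c(2, 3, 4, 6, 8, 9)) / sqrt(2)) - 1) < 0.001))

  hot <- gen_saxs_series(sc, temperatures = 66, seed = 7)[[1]]
  pkh <- detect_peaks(hot)
  expect_length(pkh$positions, 3L)
  expect_true(all(abs(sort(pkh$positions) / min(pkh$positions) /
                        c(1, sqrt(3), 2) - 1) < 0.001))
})

test_that("the excess-water preset is faster than the anhydrous-side preset everywhere", {
  sc70 <- scenario_m70w30()
  sc55 <- scenario_m55w45()
  for (Tc in seq(31, 70, by = 3)) {
    expect_true(all(scheduled_tau_max(sc55, Tc) < scheduled_tau_max(sc70, Tc)))
  }
  # process 1 spans the published ranges
  expect_equal(max(scheduled_tau_max(sc70, 31)[1]), 100, tolerance = 1e-9)
  expect_equal(scheduled_tau_max(sc70, 70)[1], 0.1, tolerance = 1e-9)
  expect_equal(scheduled_tau_max(sc55, 31)[1], 0.1, tolerance = 1e-9)
  expect_equal(scheduled_tau_max(sc55, 70)[1], 0.001, tolerance = 1e-9)
})

test_that("scheduled water populations always sum to one", {
  for (sc in list(scenario_m70w30(), scenario_m55w45())) {
    for (Tc in seq(28, 70, by = 3))
      expect_equal(sum(scheduled_phi(sc, Tc)), 1, tolerance = 1e-12)
  }
})

test_that("phase, relaxation and band schedules place the transition consistently", {
  for (sc in list(scenario_m70w30(), scenario_m55w45())) {
    w <- sc$transition_window
    expect_true(sc$kink_temperature >= w[1] && sc$kink_temperature <= w[2])
    expect_equal(scheduled_phase(sc, w[1] - 1)$phases, "Pn3m")
    expect_equal(scheduled_phase(sc, w[2] + 1)$phases, "HII")
    expect_setequal(scheduled_phase(sc, mean(w))$phases, c("Pn3m", "HII"))
  }
})

test_that("the scheduled CH2 blue shift across the series is one wavenumber", {
  sc <- scenario_m70w30()
  b30 <- scheduled_bands(sc, 30)
  b66 <- scheduled_bands(sc, 66)
  shift <- b66$center[b66$label == "CH2_sym"] - b30$center[b30$label == "CH2_sym"]
  expect_equal(shift, 1, tolerance = 1e-9)
})

test_that("zero-noise generation round-trips through the fitters", {
  sc <- scenario_m70w30()
  sp <- gen_bds_series(sc, temperatures = 52, noise = 0, seed = 1)[[1]]
  fit <- fit_spectrum(sp, n_processes = 3, seed = 1)
  expect_true(all(abs(fit$tau_max / scheduled_tau_max(sc, 52) - 1) < 1e-3))

  fs <- gen_ftir_series(sc, temperatures = 52, noise = 0, seed = 1)[[1]]
  fb <- fit_band(fs, "carbonyl", seed = 1)
  sched <- scheduled_bands(sc, 52)
  expect_equal(fb$components$center,
               sched$center[match(fb$components$label, sched$label)],
               tolerance = 1e-3)
})
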