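test_that("baseline subtraction removes flat and linear backgrounds and is idempotent", {
  w <- seq(1680, 1780, by = 2)
  region <- band_regions("carbonyl")

  flat <- ftir_spectrum(w, rep(0.4, length(w)))
  expect_true(all(abs(subtract_baseline(flat, region)$absorbance) < 1e-12))

  ramp <- ftir_spectrum(w, 0.1 + 0.002 * (w - 1680))
  expect_true(all(abs(subtract_baseline(ramp, region)$absorbance) < 1e-12))

  gauss <- 0.5 * exp(-0.5 * ((w - 1730) / 8)^2)
  spec <- ftir_spectrum(w, gauss + 0.1 + 0.002 * (w - 1680))
  corr <- subtract_baseline(spec, region)
  expect_true(all(abs(corr$absorbance - gauss) < 1e-6))

  once <- subtract_baseline(spec, region)
  twice <- subtract_baseline(ftir_spectrum(once$wavenumber, once$absorbance),
                             region)
  expect_equal(twice$absorbance, once$absorbance, tolerance = 1e-10)

  expect_error(subtract_baseline(ftir_spectrum(w, gauss),
                                 band_regions("oh_stretch")),
               class = "mesokit_validation")
})

test_that("a single Gaussian with exact initialization is recovered exactly", {
  w <- seq(1680, 1780, by = 2)
  region <- band_region("single", c(1680, 1780), "peak", 1730, 8)
  spec <- ftir_spectrum(w, 0.02 + 0.6 * exp(-0.5 * ((w - 1730) / 8)^2))
  fit <- fit_band(spec, region, seed = 1)
  expect_lt(fit$residual, 1e-8)
  expect_equal(fit$components$center, 1730, tolerance = 1e-6)
  expect_equal(fit$components$amplitude, 0.6, tolerance = 1e-6)
  expect_equal(fit$components$area, 0.6 * 8 * sqrt(2 * pi), tolerance = 1e-5)
})

test_that("the overlapped carbonyl doublet is resolved to within 1 wavenumber", {
  w <- seq(1680, 1780, by = 2)
  y <- 0.5 * exp(-0.5 * ((w - 1725) / 8)^2) +
    0.4 * exp(-0.5 * ((w - 1736) / 8)^2)
  set.seed(4)
  y <- y + rnorm(length(w), 0, max(y) / 100)  # SNR 100
  fit <- fit_band(ftir_spectrum(w, y), "carbonyl", seed = 4)
  expect_lt(abs(fit$components$center[1] - 1725), 1)
  expect_lt(abs(fit$components$center[2] - 1736), 1)
})

test_that("the OH-stretch deconvolution recovers preset centres, areas and populations", {
  sc <- scenario_m70w30()
  spec <- gen_ftir_series(sc, temperatures = 30, seed = 6)[[1]]
  fit <- fit_band(spec, "oh_stretch", seed = 6)
  sched <- scheduled_bands(sc, 30)
  for (lb in c("OH_strong", "OH_less", "OH_weak")) {
    i <- match(lb, fit$components$label)
    j <- match(lb, sched$label)
    expect_lt(abs(fit$components$center[i] - sched$center[j]), 5)
    truth_area <- sched$amplitude[j] * sched$width[j] * sqrt(2 * pi)
    expect_lt(abs(fit$components$area[i] / truth_area - 1), 0.05)
  }
  wf <- water_fractions(fit)
  expect_equal(sum(wf$phi), 1, tolerance = 1e-9)
  expect_true(all(abs(wf$phi - scheduled_phi(sc, 30)) < 0.03))
})

test_that("water fractions and carbonyl ratios follow their defining arithmetic", {
  mk_fit <- function(labels, centers, widths, amps, region) {
    structure(list(region = band_regions(region),
                   components = data.frame(label = labels, center = centers,
                                           width = widths, amplitude = amps,
                                           area = amps * widths * sqrt(2 * pi)),
                   baseline = c(intercept = 0, slope = 0), residual = 0,
                   temperature = NA_real_, converged = TRUE,
                   flags = character(0)),
              class = "band_fit")
  }
  equal3 <- mk_fit(c("OH_strong", "OH_less", "OH_weak"),
                   c(3300, 3450, 3600), c(10, 10, 10), c(1, 1, 1),
                   "oh_stretch")
  expect_equal(unname(water_fractions(equal3)$phi), rep(1 / 3, 3))

  lone <- mk_fit(c("OH_strong", "OH_less", "OH_weak"),
                 c(3300, 3450, 3600), c(10, 10, 10), c(2, 0, 0),
                 "oh_stretch")
  expect_equal(unname(water_fractions(lone)$phi), c(1, 0, 0))

  co <- mk_fit(c("CO_bonded", "CO_free"), c(1725, 1736), c(8, 8), c(4, 4),
               "carbonyl")
  expect_equal(carbonyl_ratio(co)$intensity_ratio, 1)
  co2 <- mk_fit(c("CO_bonded", "CO_free"), c(1725, 1736), c(8, 8), c(4, 2),
                "carbonyl")
  expect_equal(carbonyl_ratio(co2)$intensity_ratio, 0.5)
  co0 <- mk_fit(c("CO_bonded", "CO_free"), c(1725, 1736), c(8, 8), c(0, 2),
                "carbonyl")
  expect_error(carbonyl_ratio(co0), class = "mesokit_division")
  expect_error(water_fractions(co), class = "mesokit_validation")
})

test_that("centre trends separate linear drifts from programmed discontinuities", {
  sc70 <- scenario_m70w30()
  sc55 <- scenario_m55w45()
  temps <- seq(28, 70, by = 3)

  # M70: methylene CH centre has a programmed break near the transition
  fits70 <- lapply(gen_ftir_series(sc70, seed = 8),
                   function(s) fit_band(s, "ch_stretch", seed = 8))
  tr <- band_center_trend(fits70, "CH_methylene")
  expect_lte(abs(tr$discontinuity - 55), 3 + 3)

  # M55: water populations are linear-like, no discontinuity
  fits55 <- lapply(gen_ftir_series(sc55, seed = 8),
                   function(s) fit_band(s, "oh_stretch", seed = 8))
  phi55 <- vapply(fits55, function(f) water_fractions(f)$phi[["OH_strong"]],
                  numeric(1))
  expect_true(is.na(detect_breakpoint(temps, phi55)$breakpoint))

  # M70: water populations break near 55 C (shared detector, one step)
  fits70oh <- lapply(gen_ftir_series(sc70, seed = 8),
                     function(s) fit_band(s, "oh_stretch", seed = 8))
  phi70 <- vapply(fits70oh, function(f) water_fractions(f)$phi[["OH_strong"]],
                  numeric(1))
  bp <- detect_breakpoint(temps, phi70)
  expect_lte(abs(bp$breakpoint - 55), 3)
})

test_that("adding a component never worsens the fit objective", {
  sc <- scenario_m70w30()
  spec <- gen_ftir_series(sc, temperatures = 40, seed = 3)[[1]]
  two <- band_regions("carbonyl")
  three <- band_region("carbonyl3", c(1680, 1780),
                       c("CO_bonded", "CO_mid", "CO_free"),
                       c(1725, 1730, 1736), c(8, 8, 8))
  f2 <- fit_band(spec, two, seed = 2)
  f3 <- fit_band(spec, three, seed = 2)
  expect_lte(f3$residual, f2$residual * (1 + 1e-6))
})

test_that("centre recovery bias stays below 2 wavenumbers at SNR 50 and 1.5-sigma separation", {
  w <- seq(1680, 1780, by = 2)
  region <- band_region("pair", c(1680, 1780), c("lo", "hi"),
                        c(1722, 1734), c(8, 8))
  errs <- sapply(1:6, function(s) {
    set.seed(200 + s)
    y <- 0.5 * exp(-0.5 * ((w - 1722) / 8)^2) +
      0.45 * exp(-0.5 * ((w - 1734) / 8)^2)
    y <- y + rnorm(length(w), 0, max(y) / 50)
    fit <- fit_band(ftir_spectrum(w, y), region, seed = s)
    abs(fit$components$center - c(1722, 1734))
  })
  expect_true(all(apply(errs, 1, stats::median) < 2))
})
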