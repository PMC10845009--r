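test_that("the HN model matches static limits, the Debye midpoint, and polar-form arithmetic", {
  m <- dielectric_model(hn_process(5, 1e-3), eps_inf = 2)
  lowf <- evaluate_model(m, 1e-9)
  expect_equal(lowf$eps_real, 7, tolerance = 1e-6)
  expect_equal(lowf$eps_imag, 0, tolerance = 1e-4)

  # Debye at omega*tau = 1
  at1 <- evaluate_model(m, 1 / (2 * pi * 1e-3))
  expect_equal(at1$eps_imag, 2.5, tolerance = 1e-10)
  expect_equal(at1$eps_real, 2 + 2.5, tolerance = 1e-10)

  # general exponents against the independent polar-form evaluation
  mh <- dielectric_model(hn_process(3, 1e-3, alpha = 0.8, gamma = 0.6),
                         eps_inf = 2)
  sp <- evaluate_model(mh, 100)
  orc <- oracle_hn_polar(100, 3, 1e-3, 0.8, 0.6, eps_inf = 2)
  expect_equal(sp$eps_real, orc$re, tolerance = 1e-12)
  expect_equal(sp$eps_imag, orc$im, tolerance = 1e-12)

  expect_error(hn_process(1, 1, alpha = 1.2), class = "mesokit_validation")
  expect_error(hn_process(1, 1, alpha = 1, gamma = 1.5),
               class = "mesokit_validation")
})

test_that("the loss tangent behaves pointwise and peaks where the closed form says", {
  sp <- dielectric_spectrum(c(1, 10), c(2, 2), c(1, 0))
  expect_equal(tan_delta(sp), c(0.5, 0))

  expect_equal(debye_tan_delta_peak(0, 1), 1)
  expect_equal(debye_tan_delta_peak(1, 1), sqrt(2))
  expect_equal(debye_tan_delta_peak(3, 1), 2)
  for (case in list(c(1, 1), c(3, 1), c(5, 2))) {
    expect_equal(oracle_debye_tan_peak_grid(case[1], case[2]),
                 debye_tan_delta_peak(case[1], case[2]), tolerance = 1e-3)
  }
  expect_error(debye_tan_delta_peak(1, 0), class = "mesokit_validation")
})

test_that("the tau_max closed form agrees with grid-search argmax of the loss", {
  expect_equal(tau_max_from_hn(hn_process(1, 0.01)), 0.01)
  # symmetric Cole-Cole keeps tau_max = tau_hn
  expect_equal(tau_max_from_hn(hn_process(1, 1, alpha = 0.5)), 1,
               tolerance = 1e-12)
  for (case in list(c(0.8, 0.6), c(0.5, 0.9), c(1, 0.3))) {
    p <- hn_process(2, 1, alpha = case[1], gamma = case[2])
    expect_equal(tau_max_from_hn(p),
                 oracle_tau_max_grid(1, case[1], case[2]), tolerance = 1e-3)
  }
})

test_that("the tan-delta peak of a Debye process sits above the loss peak", {
  f <- 10^seq(-3, 3, length.out = 4000)
  for (deps in c(0.5, 2, 10)) {
    m <- dielectric_model(hn_process(deps, 1 / (2 * pi)), eps_inf = 1.5)
    sp <- evaluate_model(m, f)
    expect_gt(f[which.max(tan_delta(sp))], f[which.max(sp$eps_imag)])
  }
})

test_that("single-process and conductivity-only spectra are recovered quantitatively", {
  f <- 10^seq(-2, 6, length.out = 113)
  truth <- dielectric_model(hn_process(8, 1e-2), eps_inf = 3, sigma = 1e-11)
  set.seed(1)
  sp <- evaluate_model(truth, f)
  sp$eps_real <- sp$eps_real * (1 + rnorm(113, 0, 0.005))
  sp$eps_imag <- sp$eps_imag * (1 + rnorm(113, 0, 0.005))
  fit <- fit_spectrum(sp, n_processes = 1, representation = "eps_imag",
                      seed = 1)
  p <- fit$model$processes[[1]]
  expect_lt(abs(p$delta_eps / 8 - 1), 0.02)
  expect_lt(abs(p$tau_hn / 1e-2 - 1), 0.02)
  expect_lt(abs(fit$model$sigma / 1e-11 - 1), 0.02)

  # Debye sanity: fitted loss maximum equals delta_eps / 2 within noise
  fitted_sp <- evaluate_model(fit$model, f)
  expect_lt(abs(max(fitted_sp$eps_imag - fit$model$sigma /
                      (2 * pi * f * 8.8541878128e-12)) / (p$delta_eps / 2) - 1),
            0.02)

  sigma_only <- evaluate_model(dielectric_model(eps_inf = 2, sigma = 3e-12), f)
  fit0 <- fit_spectrum(sigma_only, n_processes = 0,
                       representation = "eps_imag", seed = 1)
  expect_lt(abs(fit0$model$sigma / 3e-12 - 1), 0.01)
})

test_that("a three-process preset spectrum is recovered in the tan-delta representation", {
  sc <- scenario_m70w30()
  sp <- gen_bds_series(sc, temperatures = 40, seed = 2)[[1]]
  fit <- fit_spectrum(sp, n_processes = 3, representation = "tan_delta",
                      seed = 2)
  expect_true(all(abs(fit$tau_max / scheduled_tau_max(sc, 40) - 1) < 0.1))
})

test_that("adding conductivity leaves fitted relaxation times unchanged within 2%", {
  f <- 10^seq(-2, 6, length.out = 113)
  procs <- list(hn_process(10, 1e-1), hn_process(4, 1e-4, alpha = 0.9))
  m0 <- dielectric_model(procs, eps_inf = 2, sigma = 0)
  m1 <- dielectric_model(procs, eps_inf = 2, sigma = 5e-12)
  fits <- lapply(list(m0, m1), function(m) {
    set.seed(9)
    sp <- evaluate_model(m, f)
    sp$eps_real <- sp$eps_real * (1 + rnorm(113, 0, 0.005))
    sp$eps_imag <- pmax(sp$eps_imag * (1 + rnorm(113, 0, 0.005)), 0)
    fit_spectrum(sp, n_processes = 2, seed = 4)
  })
  expect_true(all(abs(fits[[2]]$tau_max / fits[[1]]$tau_max - 1) < 0.02))
})

test_that("relaxation maps track the scheduled times and flag too-short series", {
  sc <- scenario_m70w30()
  spectra <- gen_bds_series(sc, seed = 2)
  map <- build_relaxation_map(spectra, n_processes = 3, seed = 1)
  d <- map$data
  temps <- sort(unique(d$temperature))
  for (k in 1:3) {
    sched <- vapply(temps, function(Tc) scheduled_tau_max(sc, Tc)[k], numeric(1))
    fitted <- d$tau_max_s[d$process == k][order(d$temperature[d$process == k])]
    expect_true(all(abs(fitted / sched - 1) < 0.1))
  }
  expect_error(build_relaxation_map(spectra[1:2]), class = "mesokit_validation")
})

test_that("parameter recovery holds over seeded replicates at 0.5% noise", {
  sc <- scenario_m70w30()
  truth <- scheduled_tau_max(sc, 58)
  errs <- sapply(1:12, function(s) {
    sp <- gen_bds_series(sc, temperatures = 58, seed = 100 + s)[[1]]
    fit <- fit_spectrum(sp, n_processes = 3, seed = s)
    abs(fit$tau_max / truth - 1)
  })
  expect_true(all(apply(errs, 1, stats::median) < 0.1))
})

test_that("an Arrhenius series yields no kink while a programmed slope change is located", {
  temps <- seq(31, 70, by = 3)
  invT <- 1 / (temps + 273.15)
  mk_map <- function(logtau) {
    d <- data.frame(temperature = temps, process = 1L,
                    tau_max_s = 10^logtau, delta_eps = 1, alpha = 1,
                    gamma = 1, sigma = 0, eps_inf = 2, residual = 0,
                    flagged = FALSE)
    structure(list(data = d, fits = list()), class = "relaxation_map")
  }
  pure <- mk_map(-5 + 2000 * (invT - mean(invT)))
  expect_true(is.na(detect_kink(pure)$kink_temperature))

  set.seed(5)
  ib <- 1 / (55 + 273.15)
  kinked <- -2 + 3000 * (invT - ib) + 5000 * pmax(invT - ib, 0) +
    rnorm(length(temps), 0, 0.02)
  km <- detect_kink(mk_map(kinked))
  expect_lte(abs(km$kink_temperature - 55), 3)
})
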