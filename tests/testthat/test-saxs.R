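test_that("peak detection finds a single bump, ignores flat curves, refines positions", {
  q <- seq(0.5, 1.5, by = 0.005)
  bump <- saxs_pattern(q, 1 + 10 * exp(-0.5 * ((q - 1) / 0.02)^2))
  pk <- detect_peaks(bump)
  expect_length(pk$positions, 1L)
  expect_lt(abs(pk$positions - 1), 0.005)

  flat <- saxs_pattern(q, rep(3, length(q)))
  expect_length(detect_peaks(flat)$positions, 0L)

  expect_error(saxs_pattern(rev(q), rep(1, length(q))),
               class = "mesokit_validation")
})

test_that("peaks of a noisy cubic pattern match the generating positions within 0.5%", {
  qhkl <- test_q_positions("Pn3m", 10)
  pat <- make_test_pattern(qhkl, noise = 0.01, seed = 7)
  pk <- detect_peaks(pat)
  expect_length(pk$positions, 6L)
  expect_true(all(abs(pk$positions / qhkl - 1) < 0.005))
})

test_that("ratio rules index cubic and hexagonal peak sets as published", {
  pn <- index_phase(0.9 * sqrt(c(2, 3, 4, 6, 8, 9)))
  expect_equal(pn$phases, "Pn3m")
  expect_equal(nrow(pn$matched$Pn3m), 6L)
  expect_lt(pn$residual["Pn3m"], 1e-10)

  hx <- index_phase(1.2 * sqrt(c(1, 3, 4)))
  expect_equal(hx$phases, "HII")
  expect_equal(nrow(hx$matched$HII), 3L)

  expect_error(index_phase(1.0), class = "mesokit_ambiguous")
  expect_error(index_phase(c(1, 1.5), tolerance = 0.001),
               class = "mesokit_unindexed")
})

test_that("greedy two-phase decomposition recovers the exhaustive-oracle partition", {
  pos_a <- test_q_positions("Pn3m", 9.5)
  pos_b <- test_q_positions("HII", 5.5)
  peaks <- sort(c(pos_a, pos_b))
  asg <- index_phase(peaks, tolerance = 0.015)
  expect_setequal(asg$phases, c("Pn3m", "HII"))
  expect_equal(sort(asg$matched$Pn3m$q), sort(pos_a), tolerance = 1e-9)
  expect_equal(sort(asg$matched$HII$q), sort(pos_b), tolerance = 1e-9)

  oracle <- oracle_two_phase_partition(peaks, saxs_rules(c("Pn3m", "HII")),
                                       0.015)
  expect_setequal(oracle$phases, asg$phases)
  ref <- if (oracle$phases[1] == "Pn3m") oracle$peaks_a else oracle$peaks_b
  expect_equal(sort(asg$matched$Pn3m$q), ref, tolerance = 1e-9)
})

test_that("lattice parameters invert the generating formulas", {
  asg <- index_phase(test_q_positions("Pn3m", 10))
  expect_equal(unname(asg$lattice_parameters["Pn3m"]), 10, tolerance = 1e-10)

  hx <- index_phase(test_q_positions("HII", 6))
  expect_equal(unname(hx$lattice_parameters["HII"]), 6, tolerance = 1e-10)

  # 0.5% multiplicative jitter: compare against a direct regression oracle
  set.seed(3)
  qj <- test_q_positions("Pn3m", 10) * (1 + rnorm(6, 0, 0.005))
  qj <- sort(qj)
  asg_j <- fit_lattice_parameter(index_phase(qj))
  m <- sqrt(c(2, 3, 4, 6, 8, 9))
  a_oracle <- 2 * pi / (sum(m * qj) / sum(m^2))
  expect_equal(unname(asg_j$lattice_parameters["Pn3m"]), a_oracle,
               tolerance = 1e-9)
  expect_lt(abs(asg_j$lattice_parameters["Pn3m"] / 10 - 1), 0.005)
})

test_that("indexing is scale invariant and round-trips the generator", {
  peaks <- test_q_positions("Pn3m", 8.7)
  a1 <- index_phase(peaks)
  a2 <- index_phase(peaks * 3.1)
  expect_equal(a1$phases, a2$phases)
  expect_equal(unname(a1$residual), unname(a2$residual), tolerance = 1e-9)
  expect_equal(unname(a2$lattice_parameters), unname(a1$lattice_parameters) / 3.1,
               tolerance = 1e-9)

  # round trip at 1% noise stays within tolerance
  pat <- make_test_pattern(test_q_positions("HII", 6.2), noise = 0.01, seed = 5)
  asg <- index_phase(detect_peaks(pat))
  expect_equal(asg$phases, "HII")
  expect_lt(abs(asg$lattice_parameters["HII"] / 6.2 - 1), 0.01)
})

test_that("full cubic and hexagonal peak sets are never cross-assigned at 1.5% tolerance", {
  rules <- saxs_rules(c("Pn3m", "HII"))
  for (a in c(6, 8, 10)) {
    expect_equal(index_phase(test_q_positions("Pn3m", a), rules,
                             two_phase = FALSE)$phases, "Pn3m")
    expect_equal(index_phase(test_q_positions("HII", a * 0.6), rules,
                             two_phase = FALSE)$phases, "HII")
  }
})

test_that("the swelling plateau is located at the boundary composition", {
  wt <- seq(25, 50, by = 2.5)
  a <- ifelse(wt <= 40, 9 + 0.08 * (wt - 25), 9 + 0.08 * 15)
  res <- detect_excess_water_boundary(wt, a)
  expect_equal(res$boundary, 40)
  expect_gt(res$pre_slope, 0)

  # strictly increasing: no plateau
  res2 <- detect_excess_water_boundary(wt, 9 + 0.08 * (wt - 25))
  expect_true(is.na(res2$boundary))

  # noisy series agrees with the exhaustive scan and stays within one step
  set.seed(11)
  an <- a * (1 + rnorm(length(a), 0, 0.003))
  res3 <- detect_excess_water_boundary(wt, an)
  expect_equal(res3$boundary, oracle_plateau_scan(wt, an))
  expect_lte(abs(res3$boundary - 40), 2.5)

  expect_error(detect_excess_water_boundary(rev(wt), a),
               class = "mesokit_validation")
})

test_that("the phase diagram reproduces the programmed bands and boundary drift", {
  sc <- scenario_m70w30()
  # grid over compositions and temperatures built from the scenario laws
  wts <- seq(28, 48, by = 4)
  temps <- c(30, 42, 54, 66)
  pats <- list()
  for (Tc in temps) for (wt in wts) {
    ph <- scheduled_phase(sc, Tc)
    pos <- c(); amp <- c()
    for (p in ph$phases) {
      frac <- if (p == "HII") ph$hex_fraction else 1 - ph$hex_fraction
      qp <- test_q_positions(p, scheduled_lattice(sc, Tc, wt, p))
      pos <- c(pos, qp)
      amp <- c(amp, 100 * seq_along(qp)^-0.8 * max(frac, 1e-6))
    }
    o <- order(pos)
    pats[[length(pats) + 1L]] <- make_test_pattern(pos[o], amp[o],
                                                   noise = 0.01,
                                                   seed = length(pats) + 1L,
                                                   temperature = Tc,
                                                   water_wt = wt)
  }
  pd <- build_phase_diagram(pats)
  g <- pd$grid
  expect_true(all(g$phase[g$temperature < 50] == "Pn3m"))
  expect_true(all(grepl("\\+", g$phase[g$temperature == 54])))
  expect_true(all(g$phase[g$temperature == 66] == "HII"))

  # boundary per temperature follows the non-increasing schedule
  b <- pd$boundary$boundary_wt[pd$boundary$temperature < 66]
  sched_b <- vapply(pd$boundary$temperature[pd$boundary$temperature < 66],
                    function(Tc) excess_boundary_wt(sc, Tc), numeric(1))
  expect_true(all(abs(b - sched_b) <= 4))
  expect_true(all(diff(b) <= 0))

  # excess flag is a step function of composition in every temperature row
  for (Tc in temps) {
    ex <- g$excess_water[g$temperature == Tc][order(g$water_wt[g$temperature == Tc])]
    expect_true(all(diff(as.integer(ex)) >= 0))
  }
})

test_that("uniform single-phase grids yield no coexistence and unindexable points do not abort", {
  pats <- list(
    make_test_pattern(test_q_positions("HII", 6), temperature = 30, water_wt = 40),
    make_test_pattern(test_q_positions("HII", 5.9), temperature = 40, water_wt = 40))
  pd <- build_phase_diagram(pats)
  expect_true(all(pd$grid$phase == "HII"))
  expect_null(coexistence_window(pd))

  q <- seq(0.3, 3, by = 0.002)
  pats2 <- c(pats, list(saxs_pattern(q, rep(1, length(q)), temperature = 50,
                                     water_wt = 40)))
  pd2 <- build_phase_diagram(pats2)
  expect_equal(pd2$grid$phase[3], "unindexed")
})
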