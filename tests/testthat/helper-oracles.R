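# Independent oracles used to cross-check the implementation. These follow
# different routes than the package code: polar-form complex arithmetic for
# the HN function, dense grid searches for peak positions, and exhaustive
# enumeration for peak partitions and breakpoints.

EPSF <- 8.8541878128e-12

# HN permittivity via the real/imaginary polar decomposition (no complex
# powers), the textbook closed form.
oracle_hn_polar <- function(f, delta_eps, tau, alpha, gamma, eps_inf = 0,
                            sigma = 0) {
  w <- 2 * pi * f
  wt <- (w * tau)^alpha
  r <- (1 + 2 * wt * cos(pi * alpha / 2) + wt^2)^(gamma / 2)
  psi <- atan2(wt * sin(pi * alpha / 2), 1 + wt * cos(pi * alpha / 2))
  list(re = eps_inf + delta_eps * cos(gamma * psi) / r,
       im = delta_eps * sin(gamma * psi) / r + sigma / (w * EPSF))
}

# tau at maximum loss by dense log-grid search on the loss curve.
oracle_tau_max_grid <- function(tau, alpha, gamma, n = 2e5) {
  f <- 10^seq(log10(1 / tau) - 6, log10(1 / tau) + 6, length.out = n)
  im <- oracle_hn_polar(f, 1, tau, alpha, gamma)$im
  1 / (2 * pi * f[which.max(im)])
}

# omega*tau at the Debye loss-tangent maximum by dense grid search.
oracle_debye_tan_peak_grid <- function(delta_eps, eps_h, n = 4e5) {
  f <- 10^seq(-4, 4, length.out = n)   # tau = 1
  e <- oracle_hn_polar(f, delta_eps, 1, 1, 1, eps_inf = eps_h)
  2 * pi * f[which.max(e$im / e$re)]
}

# Exhaustive two-phase peak partition: every rule pair, every anchor
# assignment; maximizes total matched peaks (ties by total residual).
oracle_two_phase_partition <- function(positions, rules, tolerance) {
  match_anchored <- function(pos, rule, anchor) {
    ratios <- rule$spacing_ratios / rule$spacing_ratios[1]
    target <- anchor * ratios
    used <- rep(FALSE, length(pos))
    hit <- integer(0); slot <- integer(0)
    for (j in seq_along(target)) {
      dev <- abs(pos / target[j] - 1); dev[used] <- Inf
      i <- which.min(dev)
      if (is.finite(dev[i]) && dev[i] <= tolerance) {
        used[i] <- TRUE; hit <- c(hit, i); slot <- c(slot, j)
      }
    }
    list(hit = hit, slot = slot)
  }
  rms_resid <- function(pos, rule, m) {
    if (!length(m$hit)) return(Inf)
    mod <- rule$spacing_ratios[m$slot]; qv <- pos[m$hit]
    slope <- sum(mod * qv) / sum(mod^2)
    sqrt(mean((qv / (slope * mod) - 1)^2))
  }
  best <- NULL
  for (ia in seq_along(rules)) for (ib in seq_along(rules)) {
    if (ia == ib) next
    for (pa in positions) {
      ma <- match_anchored(positions, rules[[ia]], pa)
      if (length(ma$hit) < 2) next
      left <- positions[-ma$hit]
      if (length(left) < 2) next
      for (pb in left) {
        mb <- match_anchored(left, rules[[ib]], pb)
        if (length(mb$hit) < 2) next
        tot <- length(ma$hit) + length(mb$hit)
        res <- rms_resid(positions, rules[[ia]], ma) +
          rms_resid(left, rules[[ib]], mb)
        if (is.null(best) || tot > best$tot ||
            (tot == best$tot && res < best$res)) {
          best <- list(tot = tot, res = res,
                       phases = c(rules[[ia]]$phase_label,
                                  rules[[ib]]$phase_label),
                       peaks_a = sort(positions[ma$hit]),
                       peaks_b = sort(left[mb$hit]))
        }
      }
    }
  }
  best
}

# Exhaustive breakpoint scan minimizing SSE of the continuous hinge model.
oracle_breakpoint_scan <- function(x, y, min_segment = 3L) {
  o <- order(x); x <- x[o]; y <- y[o]
  n <- length(x)
  best <- NULL
  for (k in seq.int(min_segment, n - min_segment + 1L)) {
    X <- cbind(1, x, pmax(x - x[k], 0))
    sse <- sum(stats::lm.fit(X, y)$residuals^2)
    if (is.null(best) || sse < best$sse) best <- list(k = k, sse = sse)
  }
  x[best$k]
}

# Exhaustive increase-then-plateau breakpoint scan.
oracle_plateau_scan <- function(x, y, min_plateau = 2L) {
  n <- length(x)
  best <- NULL
  for (k in seq.int(2L, n - min_plateau + 1L)) {
    X <- cbind(1, pmin(x - x[k], 0))
    sse <- sum(stats::lm.fit(X, y)$residuals^2)
    if (is.null(best) || sse < best$sse) best <- list(k = k, sse = sse)
  }
  x[best$k]
}

# Simple Lorentzian-peak pattern builder for SAXS tests, independent of the
# scenario machinery.
make_test_pattern <- function(positions, amplitudes = NULL,
                              q = seq(0.3, 3, by = 0.002), hwhm = 0.01,
                              noise = 0, seed = NULL,
                              temperature = NA, water_wt = NA) {
  if (is.null(amplitudes)) amplitudes <- 100 * seq_along(positions)^-0.8
  y <- 5 * q^-1.5 + 1
  for (j in seq_along(positions))
    y <- y + amplitudes[j] * hwhm^2 / ((q - positions[j])^2 + hwhm^2)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y * (1 + stats::rnorm(length(q), 0, noise))
  }
  saxs_pattern(q, pmax(y, 0), temperature, water_wt)
}

# q positions of a phase's allowed reflections at lattice parameter a.
test_q_positions <- function(phase, a) {
  r <- saxs_rules(phase)[[1]]
  if (r$geometry == "hexagonal") 4 * pi * r$spacing_ratios / (sqrt(3) * a)
  else 2 * pi * r$spacing_ratios / a
}
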