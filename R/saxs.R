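#' Construct a 1-D SAXS powder pattern
#'
#' @param q scattering vector grid in nm^-1, strictly increasing.
#' @param intensity nonnegative intensities (arbitrary units), same length
#'   as `q`.
#' @param temperature sample temperature in deg C (metadata).
#' @param water_wt water mass fraction of the sample in percent (metadata).
#' @return An object of class `"saxs_pattern"` (a list with the validated
#'   fields).
#' @export
saxs_pattern <- function(q, intensity, temperature = NA_real_,
                         water_wt = NA_real_) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop_mesokit("q and intensity must have the same length", "mesokit_validation")
  if (!is_strictly_increasing(q))
    stop_mesokit("q grid must be strictly increasing", "mesokit_validation")
  if (any(intensity < 0))
    stop_mesokit("intensity must be nonnegative", "mesokit_validation")
  if (!is.na(water_wt) && (water_wt < 0 || water_wt > 100))
    stop_mesokit("water_wt must lie in [0, 100]", "mesokit_validation")
  structure(list(q = q, intensity = intensity,
                 temperature = as.numeric(temperature),
                 water_wt = as.numeric(water_wt)),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat(sprintf("SAXS pattern: %d points, q in [%.3g, %.3g] nm^-1, T = %s C, water = %s wt%%\n",
              length(x$q), min(x$q), max(x$q),
              format(x$temperature), format(x$water_wt)))
  invisible(x)
}

#' Bragg spacing-ratio rules for lyotropic phases
#'
#' Returns the reflection-ratio rule set used to index powder patterns.
#' Spacing ratios are quoted relative to the lowest allowed reflection of
#' each phase: Pn3m at sqrt(2):sqrt(3):sqrt(4):sqrt(6):sqrt(8):sqrt(9),
#' HII (reverse hexagonal) at 1:sqrt(3):sqrt(4), Ia3d at
#' sqrt(6):sqrt(8):sqrt(14):sqrt(16):sqrt(20):sqrt(22). The primitive cubic
#' Im3m (sqrt(2):sqrt(4):sqrt(6)) and lamellar (1:2:3) rules are available
#' but excluded from the default set.
#'
#' @param phases character vector of phase labels to include. Defaults to
#'   the three phases relevant to the monolinolein-water system.
#' @return A list of `"ratio_rule"` objects with fields `phase_label`,
#'   `spacing_ratios` (absolute sqrt-N moduli), `miller` (index strings),
#'   and `geometry`.
#' @export
saxs_rules <- function(phases = c("Pn3m", "HII", "Ia3d")) {
  all_rules <- list(
    Pn3m = ratio_rule("Pn3m", sqrt(c(2, 3, 4, 6, 8, 9)),
                      c("110", "111", "200", "211", "220", "221"), "cubic"),
    HII  = ratio_rule("HII", sqrt(c(1, 3, 4)), c("10", "11", "20"), "hexagonal"),
    Ia3d = ratio_rule("Ia3d", sqrt(c(6, 8, 14, 16, 20, 22)),
                      c("211", "220", "321", "400", "420", "332"), "cubic"),
    Im3m = ratio_rule("Im3m", sqrt(c(2, 4, 6)), c("110", "200", "211"), "cubic"),
    La   = ratio_rule("La", c(1, 2, 3), c("1", "2", "3"), "lamellar")
  )
  unknown <- setdiff(phases, names(all_rules))
  if (length(unknown))
    stop_mesokit(paste("unknown phase rule(s):", paste(unknown, collapse = ", ")),
                 "mesokit_validation")
  all_rules[phases]
}

#' @rdname saxs_rules
#' @param phase_label phase name.
#' @param spacing_ratios allowed-reflection moduli, ascending; for cubic
#'   phases these are sqrt(h^2+k^2+l^2), for hexagonal sqrt(h^2+hk+k^2).
#' @param miller reflection index strings matching `spacing_ratios`.
#' @param geometry one of `"cubic"`, `"hexagonal"`, `"lamellar"`.
#' @export
ratio_rule <- function(phase_label, spacing_ratios, miller, geometry) {
  geometry <- match.arg(geometry, c("cubic", "hexagonal", "lamellar"))
  if (is.unsorted(spacing_ratios, strictly = TRUE))
    stop_mesokit("spacing_ratios must be strictly ascending", "mesokit_validation")
  if (length(spacing_ratios) != length(miller))
    stop_mesokit("spacing_ratios and miller lengths differ", "mesokit_validation")
  structure(list(phase_label = phase_label,
                 spacing_ratios = as.numeric(spacing_ratios),
                 miller = as.character(miller),
                 geometry = geometry),
            class = "ratio_rule")
}

#' Detect Bragg peaks in a SAXS pattern
#'
#' Smooths the curve with a centred moving average, takes local maxima whose
#' topographic prominence exceeds `min_prominence` times the maximum smoothed
#' intensity, and refines each position by a 3-point parabolic interpolation
#' on the log-intensity.
#'
#' @param pattern a [saxs_pattern()].
#' @param min_prominence required prominence as a fraction of the maximum
#'   smoothed intensity, in (0, 1).
#' @param smoothing_window moving-average window in points (odd; default 5).
#' @return An object of class `"peak_set"`: list with `positions` (nm^-1,
#'   ascending) and `prominences`. Patterns with no structure yield an empty
#'   peak set, not an error.
#' @export
detect_peaks <- function(pattern, min_prominence = 0.02, smoothing_window = 5L) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  if (min_prominence <= 0 || min_prominence >= 1)
    stop_mesokit("min_prominence must lie in (0, 1)", "mesokit_validation")
  q <- pattern$q
  y <- moving_average(pattern$intensity, smoothing_window)
  empty <- structure(list(positions = numeric(0), prominences = numeric(0)),
                     class = "peak_set")
  n <- length(y)
  if (n < 3L || diff(range(y)) == 0) return(empty)

  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(is_max)) return(empty)

  # Topographic prominence: height above the higher of the two valley floors
  # reached before a taller sample in each direction.
  prom <- vapply(is_max, function(i) {
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > y[i])
    lo_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > y[i])
    lo_r <- if (length(higher_r)) min(y[i + seq_len(min(higher_r) - 1L)]) else min(right)
    y[i] - max(lo_l, lo_r)
  }, numeric(1))

  keep <- prom >= min_prominence * max(y)
  idx <- is_max[keep]
  if (!length(idx)) return(empty)

  # Parabolic refinement on log intensity.
  pos <- vapply(idx, function(i) {
    if (i <= 1L || i >= n) return(q[i])
    yy <- log(pmax(y[(i - 1L):(i + 1L)], .Machine$double.xmin))
    denom <- yy[1] - 2 * yy[2] + yy[3]
    if (denom >= 0) return(q[i])
    delta <- 0.5 * (yy[1] - yy[3]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    q[i] + delta * (q[min(i + 1L, n)] - q[max(i - 1L, 1L)]) / 2
  }, numeric(1))

  o <- order(pos)
  structure(list(positions = pos[o], prominences = prom[keep][o]),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak set:", length(x$positions), "peaks at q =",
      paste(format(x$positions, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# Match one ratio rule against peak positions anchored on `anchor` (a q
# value taken as the rule's first allowed reflection). Each rule slot takes
# at most one peak (the closest within tolerance); each peak is used once.
match_rule <- function(positions, rule, tolerance, anchor = positions[1]) {
  ratios <- rule$spacing_ratios / rule$spacing_ratios[1]
  target <- anchor * ratios
  used <- rep(FALSE, length(positions))
  slot <- integer(0); peak <- integer(0)
  for (j in seq_along(target)) {
    dev <- abs(positions / target[j] - 1)
    dev[used] <- Inf
    i <- which.min(dev)
    if (length(i) && is.finite(dev[i]) && dev[i] <= tolerance) {
      used[i] <- TRUE
      slot <- c(slot, j); peak <- c(peak, i)
    }
  }
  list(slot = slot, peak = peak, n = length(peak))
}

# Least-squares lattice parameter for a matched rule: q = slope * modulus,
# slope fitted through the origin.
lattice_from_match <- function(positions, rule, m) {
  mod <- rule$spacing_ratios[m$slot]
  qv <- positions[m$peak]
  slope <- sum(mod * qv) / sum(mod^2)
  if (!is.finite(slope) || slope <= 0)
    stop_mesokit("degenerate geometry: nonpositive fitted slope", "mesokit_degenerate")
  a <- switch(rule$geometry,
              cubic = 2 * pi / slope,
              hexagonal = 4 * pi / (sqrt(3) * slope),
              lamellar = 2 * pi / slope)
  resid <- sqrt(mean((qv / (slope * mod) - 1)^2))
  list(a = a, residual = resid, slope = slope)
}

#' Assign lyotropic phase(s) to a set of Bragg peaks
#'
#' Single-phase mode scores every rule by the number of observed positions
#' whose ratio to the first peak matches an allowed spacing ratio within
#' `tolerance`; ties are broken by the smaller lattice-fit residual. When
#' `two_phase = TRUE` the assignment is greedy: the winning rule claims its
#' matched peaks, the leftovers are re-indexed against the remaining rules
#' (anchored on the first leftover peak), and coexistence is reported when
#' the second rule matches at least `min_second_matches` peaks.
#'
#' @param peaks a `"peak_set"` from [detect_peaks()], or a numeric vector of
#'   peak positions.
#' @param rules list of [ratio_rule()] objects (default [saxs_rules()]).
#' @param tolerance maximum relative deviation of a matched ratio, in
#'   (0, 0.05].
#' @param two_phase attempt a greedy two-phase decomposition.
#' @param min_second_matches leftover peaks the second phase must match.
#' @return An object of class `"phase_assignment"`: `phases` (1 or 2
#'   labels), `matched` (per phase, data frame of q, miller index and
#'   modulus), `lattice_parameters` (nm, named by phase), `residual` (rms
#'   relative deviation, named by phase), `unmatched` (leftover positions).
#' @export
index_phase <- function(peaks, rules = saxs_rules(), tolerance = 0.015,
                        two_phase = TRUE, min_second_matches = 2L) {
  positions <- if (inherits(peaks, "peak_set")) peaks$positions else as.numeric(peaks)
  if (tolerance <= 0 || tolerance > 0.05)
    stop_mesokit("tolerance must lie in (0, 0.05]", "mesokit_validation")
  if (length(positions) < 2L)
    stop_mesokit("ambiguous: need at least 2 peaks to index a phase",
                 "mesokit_ambiguous")

  pick_best <- function(pos, rls) {
    best <- NULL
    for (rule in rls) {
      m <- match_rule(pos, rule, tolerance)
      if (m$n < 2L) next
      lat <- lattice_from_match(pos, rule, m)
      # ties on matched count go to the rule whose matched slots are the
      # more contiguous low-order sequence (fewer skipped allowed
      # reflections below the highest matched one), then to the smaller
      # residual: a 1:sqrt(3):2 triplet is the hexagonal 10/11/20 series,
      # not a cubic set with missing reflections.
      skips <- max(m$slot) - m$n
      better <- is.null(best) || m$n > best$n ||
        (m$n == best$n && skips < best$skips) ||
        (m$n == best$n && skips == best$skips &&
           lat$residual < best$lat$residual)
      if (better)
        best <- list(rule = rule, m = m, lat = lat, n = m$n, skips = skips)
    }
    best
  }

  first <- pick_best(positions, rules)
  if (is.null(first))
    stop_mesokit("unindexed: no rule matches at least 2 peaks",
                 "mesokit_unindexed")

  phases <- first$rule$phase_label
  matched <- list()
  matched[[phases]] <- data.frame(
    q = positions[first$m$peak],
    miller = first$rule$miller[first$m$slot],
    modulus = first$rule$spacing_ratios[first$m$slot],
    stringsAsFactors = FALSE)
  lattice <- stats::setNames(first$lat$a, phases)
  residual <- stats::setNames(first$lat$residual, phases)
  leftover <- positions[-first$m$peak]

  if (two_phase && length(leftover) >= min_second_matches) {
    rest <- Filter(function(r) r$phase_label != first$rule$phase_label, rules)
    second <- pick_best(leftover, rest)
    if (!is.null(second) && second$n >= min_second_matches) {
      lbl <- second$rule$phase_label
      phases <- c(phases, lbl)
      matched[[lbl]] <- data.frame(
        q = leftover[second$m$peak],
        miller = second$rule$miller[second$m$slot],
        modulus = second$rule$spacing_ratios[second$m$slot],
        stringsAsFactors = FALSE)
      lattice[lbl] <- second$lat$a
      residual[lbl] <- second$lat$residual
      leftover <- leftover[-second$m$peak]
    }
  }

  structure(list(phases = phases, matched = matched,
                 lattice_parameters = lattice, residual = residual,
                 unmatched = leftover, tolerance = tolerance),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("phase assignment:", paste(x$phases, collapse = " + "), "\n")
  for (ph in x$phases) {
    cat(sprintf("  %s: a = %.4g nm, %d reflections, rms resid %.2e\n",
                ph, x$lattice_parameters[ph], nrow(x$matched[[ph]]),
                x$residual[ph]))
  }
  if (length(x$unmatched))
    cat("  unmatched peaks:", paste(format(x$unmatched, digits = 4),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Refit lattice parameters for an existing phase assignment
#'
#' Re-runs the least-squares slope fit of peak position versus reflection
#' modulus (through the origin) for every phase in the assignment and
#' updates lattice parameters and residuals. For cubic phases
#' q = 2*pi*sqrt(h^2+k^2+l^2)/a, for hexagonal
#' q = (4*pi/(sqrt(3)*a))*sqrt(h^2+hk+k^2).
#'
#' @param assignment a `"phase_assignment"`.
#' @param peaks optionally, a `"peak_set"` whose positions replace the
#'   matched q values (matched by nearest position).
#' @return The updated assignment.
#' @export
fit_lattice_parameter <- function(assignment, peaks = NULL) {
  stopifnot(inherits(assignment, "phase_assignment"))
  for (ph in assignment$phases) {
    df <- assignment$matched[[ph]]
    if (!nrow(df))
      stop_mesokit("assignment has no matched peaks for phase", "mesokit_validation")
    qv <- df$q
    if (!is.null(peaks)) {
      pos <- if (inherits(peaks, "peak_set")) peaks$positions else as.numeric(peaks)
      qv <- vapply(qv, function(qq) pos[which.min(abs(pos - qq))], numeric(1))
    }
    geom <- if (ph %in% c("HII")) "hexagonal" else if (ph == "La") "lamellar" else "cubic"
    slope <- sum(df$modulus * qv) / sum(df$modulus^2)
    if (!is.finite(slope) || slope <= 0)
      stop_mesokit("degenerate geometry: nonpositive fitted slope",
                   "mesokit_degenerate")
    a <- switch(geom, cubic = 2 * pi / slope,
                hexagonal = 4 * pi / (sqrt(3) * slope),
                lamellar = 2 * pi / slope)
    assignment$matched[[ph]]$q <- qv
    assignment$lattice_parameters[ph] <- a
    assignment$residual[ph] <- sqrt(mean((qv / (slope * df$modulus) - 1)^2))
  }
  assignment
}

#' Locate the excess-water swelling boundary in a hydration series
#'
#' Beyond the swelling limit the lattice parameter stops growing with water
#' content: additional water stays outside the mesophase. This fits a
#' continuous increase-then-plateau model (two segments, plateau slope fixed
#' at zero, breakpoint scanned over the composition grid) and compares it
#' against a single straight line by BIC.
#'
#' @param water_wt water contents in wt%, sorted ascending (>= 4 points).
#' @param lattice_parameter lattice parameters (nm) at those compositions.
#' @param min_plateau_points minimum points the plateau must span.
#' @param min_bic_improvement required BIC advantage of the plateau model.
#' @return A list with `boundary` (wt%, or `NA` when no plateau is
#'   supported), `plateau_value` (nm), `pre_slope` (nm per wt%), and
#'   `delta_bic`.
#' @export
detect_excess_water_boundary <- function(water_wt, lattice_parameter,
                                         min_plateau_points = 2L,
                                         min_bic_improvement = 0) {
  x <- as.numeric(water_wt); y <- as.numeric(lattice_parameter)
  if (length(x) != length(y) || length(x) < 4L)
    stop_mesokit("need >= 4 (water_wt, lattice) points", "mesokit_validation")
  if (is.unsorted(x, strictly = TRUE))
    stop_mesokit("water_wt must be sorted strictly ascending", "mesokit_validation")
  n <- length(x)
  none <- list(boundary = NA_real_, plateau_value = NA_real_,
               pre_slope = NA_real_, delta_bic = NA_real_)

  fit_line <- stats::lm.fit(cbind(1, x), y)
  sse1 <- sum(fit_line$residuals^2)
  floor_sse <- max(1e-12 * sum(y^2), 1e-300)
  bic <- function(sse, k) n * log(max(sse, floor_sse) / n) + k * log(n)

  best <- NULL
  for (k in seq.int(2L, n - min_plateau_points + 1L)) {
    # plateau from x[k] onward; rising limb through (x[k], plateau)
    X <- cbind(1, pmin(x - x[k], 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, sse = sse, plateau = f$coefficients[1L],
                   slope = f$coefficients[2L])
  }
  delta <- bic(sse1, 2L) - bic(best$sse, 3L)
  if (!is.finite(delta) || delta <= min_bic_improvement || best$slope <= 0)
    return(c(none, list(delta_bic = delta)))
  list(boundary = x[best$k], plateau_value = unname(best$plateau),
       pre_slope = unname(best$slope), delta_bic = delta)
}

#' Build a temperature-composition phase diagram from SAXS patterns
#'
#' Runs peak detection, phase indexing and lattice-parameter fitting on every
#' pattern, then, for each temperature with at least four compositions,
#' locates the excess-water boundary from the primary-phase lattice
#' parameters. State points that cannot be indexed are labelled
#' `"unindexed"`; the grid is never aborted.
#'
#' @param patterns list of [saxs_pattern()] objects covering a
#'   (water_wt, temperature) grid (a single composition is accepted; the
#'   boundary is then not computed).
#' @param rules,tolerance passed to [index_phase()].
#' @param min_prominence,smoothing_window passed to [detect_peaks()].
#' @param min_plateau_points passed to [detect_excess_water_boundary()].
#' @return An object of class `"phase_diagram"`: `grid` (data frame with
#'   water_wt, temperature, phase, a_nm, a_nm_2, residual, excess_water),
#'   `boundary` (data frame temperature, boundary_wt), and `assignments`
#'   (list of per-point `"phase_assignment"` objects or `NULL`).
#' @export
build_phase_diagram <- function(patterns, rules = saxs_rules(),
                                tolerance = 0.015, min_prominence = 0.02,
                                smoothing_window = 5L,
                                min_plateau_points = 2L) {
  stopifnot(length(patterns) >= 1L)
  rows <- vector("list", length(patterns))
  assignments <- vector("list", length(patterns))
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    asg <- tryCatch({
      pk <- detect_peaks(p, min_prominence, smoothing_window)
      index_phase(pk, rules, tolerance)
    }, mesokit_error = function(e) NULL)
    assignments[[i]] <- asg
    if (is.null(asg)) {
      rows[[i]] <- data.frame(water_wt = p$water_wt, temperature = p$temperature,
                              phase = "unindexed", a_nm = NA_real_,
                              a_nm_2 = NA_real_, residual = NA_real_,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        water_wt = p$water_wt, temperature = p$temperature,
        phase = paste(asg$phases, collapse = "+"),
        a_nm = unname(asg$lattice_parameters[1L]),
        a_nm_2 = if (length(asg$phases) > 1L) unname(asg$lattice_parameters[2L]) else NA_real_,
        residual = unname(asg$residual[1L]),
        stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)

  temps <- sort(unique(grid$temperature))
  bnd <- data.frame(temperature = temps, boundary_wt = NA_real_)
  for (j in seq_along(temps)) {
    sub <- grid[grid$temperature == temps[j] & is.finite(grid$a_nm), ]
    sub <- sub[order(sub$water_wt), ]
    if (nrow(sub) >= 4L && !anyDuplicated(sub$water_wt)) {
      res <- detect_excess_water_boundary(sub$water_wt, sub$a_nm,
                                          min_plateau_points = min_plateau_points)
      bnd$boundary_wt[j] <- res$boundary
    }
  }
  bmap <- stats::setNames(bnd$boundary_wt, bnd$temperature)
  bw <- bmap[as.character(grid$temperature)]
  grid$excess_water <- !is.na(bw) & grid$water_wt >= bw

  structure(list(grid = grid, boundary = bnd, assignments = assignments),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase diagram:", nrow(x$grid), "state points,",
      length(unique(x$grid$water_wt)), "composition(s) x",
      length(unique(x$grid$temperature)), "temperature(s)\n")
  print(utils::head(x$grid, 10))
  if (nrow(x$grid) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.phase_diagram <- function(x, ...) x$grid

#' Temperature window where two phases coexist
#'
#' @param diagram a `"phase_diagram"`.
#' @param water_wt optionally restrict to one composition.
#' @return Numeric `c(lower, upper)` in deg C (grid temperatures of the
#'   first/last coexistence point), or `NULL` when no point shows two
#'   phases.
#' @export
coexistence_window <- function(diagram, water_wt = NULL) {
  g <- diagram$grid
  if (!is.null(water_wt)) g <- g[g$water_wt == water_wt, ]
  co <- g$temperature[grepl("\\+", g$phase)]
  if (!length(co)) return(NULL)
  range(co)
}
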