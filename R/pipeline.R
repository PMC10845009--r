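# Study orchestration: run the three analysis stages over one sample's
# series, aggregate per-modality transition-temperature estimates, and
# compare samples with and without excess water.

#' Run the three-modality mesophase study on one sample
#'
#' Executes SAXS phase indexing over the temperature series (and, when
#' several compositions are present, the full phase diagram with the
#' excess-water boundary), dielectric relaxation-map fitting with kink
#' detection, and FTIR region fitting with water-population and carbonyl
#' analysis plus trend-discontinuity tests. Each stage is isolated: a
#' failing stage is recorded in `errors` and the others still run. The
#' per-modality transition estimates are intersected into a consensus
#' interval.
#'
#' @param saxs list of [saxs_pattern()] objects (or a manifest path).
#' @param bds list of `"dielectric_spectrum"` objects (or a manifest path).
#' @param ftir list of [ftir_spectrum()] objects (or a manifest path).
#' @param n_processes HN processes for the dielectric stage.
#' @param rules,tolerance SAXS indexing options.
#' @param seed RNG seed for all fitting multi-starts.
#' @param n_starts multi-start count for the anchor dielectric fit.
#' @return An object of class `"study_report"` with elements
#'   `phase_series`, `phase_diagram` (when >= 2 compositions and >= 4
#'   points per temperature), `transition_window_saxs`, `relaxation_map`,
#'   `kinks` (per process), `ftir_fits`, `phi_series`, `carbonyl_series`,
#'   `trends`, `consensus` (intersection interval or disagreement flag),
#'   and `errors`.
#' @export
run_study <- function(saxs = NULL, bds = NULL, ftir = NULL,
                      n_processes = 3L, rules = saxs_rules(),
                      tolerance = 0.015, seed = 1L, n_starts = 8L) {
  if (is.character(saxs)) saxs <- read_series(saxs, "saxs")
  if (is.character(bds)) bds <- read_series(bds, "bds")
  if (is.character(ftir)) ftir <- read_series(ftir, "ftir")
  if (is.null(saxs) && is.null(bds) && is.null(ftir))
    stop_mesokit("no input series supplied", "mesokit_validation")
  errors <- list()
  report <- list(seed = seed, errors = errors)
  intervals <- list()

  if (!is.null(saxs)) {
    res <- tryCatch({
      pd <- build_phase_diagram(saxs, rules = rules, tolerance = tolerance)
      win <- coexistence_window(pd)
      list(diagram = pd, window = win)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$saxs <- conditionMessage(res)
    } else {
      report$phase_series <- res$diagram$grid
      report$phase_diagram <- res$diagram
      report$transition_window_saxs <- res$window
      if (!is.null(res$window)) intervals$saxs <- res$window
    }
  }

  if (!is.null(bds)) {
    res <- tryCatch({
      map <- build_relaxation_map(bds, n_processes = n_processes,
                                  seed = seed, n_starts = n_starts)
      temps <- sort(unique(map$data$temperature))
      step <- if (length(temps) > 1) stats::median(diff(temps)) else NA_real_
      kinks <- lapply(seq_len(n_processes), function(k)
        tryCatch(detect_kink(map, process = k)$kink_temperature,
                 error = function(e) NA_real_))
      list(map = map, kinks = unlist(kinks), step = step)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors$bds <- conditionMessage(res)
    } else {
      report$relaxation_map <- res$map
      report$kinks <- res$kinks
      k1 <- res$kinks[1]
      if (is.finite(k1) && is.finite(res$step))
        intervals$bds <- c(k1 - res$step, k1 + res$step)
    }
  }

  if (!is.null(ftir)) {
    res <- tryCatch(run_ftir_stage(ftir, seed = seed), error = function(e) e)
    if (inherits(res, "error")) {
      errors$ftir <- conditionMessage(res)
    } else {
      report <- c(report, res)
      disc <- res$phi_discontinuity
      temps <- res$phi_series$temperature
      step <- if (length(temps) > 1) stats::median(diff(sort(temps))) else NA_real_
      if (is.finite(disc) && is.finite(step))
        intervals$ftir <- c(disc - step, disc + step)
    }
  }

  if (length(intervals)) {
    lo <- max(vapply(intervals, `[`, numeric(1), 1))
    hi <- min(vapply(intervals, `[`, numeric(1), 2))
    report$consensus <- list(
      interval = if (lo <= hi) c(lo, hi) else NULL,
      agreement = lo <= hi,
      per_modality = intervals)
  }
  report$errors <- errors
  class(report) <- "study_report"
  report
}

# FTIR stage: fit the carbonyl, CH and OH regions at every temperature.
run_ftir_stage <- function(ftir, seed = 1L) {
  temps <- vapply(ftir, `[[`, numeric(1), "temperature")
  o <- order(temps)
  ftir <- ftir[o]; temps <- temps[o]
  fit_region <- function(region)
    lapply(ftir, function(sp) fit_band(sp, region, seed = seed))
  co_fits <- fit_region("carbonyl")
  ch_fits <- fit_region("ch_stretch")
  oh_fits <- fit_region("oh_stretch")

  phi <- do.call(rbind, lapply(seq_along(oh_fits), function(i) {
    wf <- water_fractions(oh_fits[[i]])
    data.frame(temperature = temps[i], phi_strong = wf$phi[["OH_strong"]],
               phi_less = wf$phi[["OH_less"]], phi_weak = wf$phi[["OH_weak"]])
  }))
  co <- do.call(rbind, lapply(seq_along(co_fits), function(i) {
    cr <- carbonyl_ratio(co_fits[[i]])
    data.frame(temperature = temps[i], intensity_ratio = cr$intensity_ratio,
               area_ratio = cr$area_ratio)
  }))
  phi_bp <- detect_breakpoint(phi$temperature, phi$phi_strong)
  ratio_slope <- unname(stats::coef(stats::lm(intensity_ratio ~ temperature,
                                              data = co))[2])
  trends <- list(
    CH2_sym = band_center_trend(ch_fits, "CH2_sym"),
    CH_methylene = band_center_trend(ch_fits, "CH_methylene"))
  list(ftir_fits = list(carbonyl = co_fits, ch_stretch = ch_fits,
                        oh_stretch = oh_fits),
       phi_series = phi, phi_discontinuity = phi_bp$breakpoint,
       carbonyl_series = co,
       carbonyl_direction = if (ratio_slope > 0) "increasing" else "decreasing",
       trends = trends)
}

#' @export
print.study_report <- function(x, ...) {
  cat("mesophase study report\n")
  if (!is.null(x$transition_window_saxs))
    cat(sprintf("  SAXS coexistence window: %g-%g C\n",
                x$transition_window_saxs[1], x$transition_window_saxs[2]))
  if (!is.null(x$kinks))
    cat("  BDS kink temperatures (per process):",
        paste(format(x$kinks, digits = 4), collapse = ", "), "C\n")
  if (!is.null(x$phi_discontinuity))
    cat("  FTIR water-population discontinuity:",
        format(x$phi_discontinuity, digits = 4), "C\n")
  if (!is.null(x$carbonyl_direction))
    cat("  carbonyl free:H-bonded ratio trend:", x$carbonyl_direction, "\n")
  if (!is.null(x$consensus)) {
    if (x$consensus$agreement)
      cat(sprintf("  consensus transition interval: %g-%g C\n",
                  x$consensus$interval[1], x$consensus$interval[2]))
    else cat("  consensus: modalities disagree\n")
  }
  if (length(x$errors))
    cat("  stage errors:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two study reports with and without excess water
#'
#' Computes, per relaxation process, the ratio of relaxation times at every
#' common temperature (report A over report B) and compares the FTIR trend
#' directions. With A the lower-hydration sample and B the excess-water
#' sample, ratios above 1 quantify the plasticizing acceleration by excess
#' water.
#'
#' @param report_a,report_b `"study_report"` objects with relaxation maps.
#' @return An object of class `"excess_water_comparison"`: `tau_ratios`
#'   (data frame process, temperature, ratio), `verdicts` (per process:
#'   `"faster_in_b"`, `"slower_in_b"` or `"mixed"`), and
#'   `carbonyl_directions`.
#' @export
compare_excess_water <- function(report_a, report_b) {
  ma <- report_a$relaxation_map$data
  mb <- report_b$relaxation_map$data
  if (is.null(ma) || is.null(mb))
    stop_mesokit("both reports need relaxation maps", "mesokit_validation")
  common <- intersect(ma$temperature, mb$temperature)
  if (!length(common))
    stop_mesokit("no common temperatures between the reports",
                 "mesokit_validation")
  procs <- intersect(unique(ma$process), unique(mb$process))
  rows <- list()
  for (k in procs) {
    for (tc in sort(common)) {
      ta <- ma$tau_max_s[ma$process == k & ma$temperature == tc]
      tb <- mb$tau_max_s[mb$process == k & mb$temperature == tc]
      rows[[length(rows) + 1L]] <-
        data.frame(process = k, temperature = tc, ratio = ta / tb)
    }
  }
  ratios <- do.call(rbind, rows)
  verdicts <- vapply(procs, function(k) {
    r <- ratios$ratio[ratios$process == k]
    if (all(r > 1)) "faster_in_b" else if (all(r < 1)) "slower_in_b" else "mixed"
  }, character(1))
  names(verdicts) <- paste0("process_", procs)
  dirs <- c(a = report_a$carbonyl_direction %||% NA_character_,
            b = report_b$carbonyl_direction %||% NA_character_)
  structure(list(tau_ratios = ratios, verdicts = verdicts,
                 carbonyl_directions = dirs),
            class = "excess_water_comparison")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.excess_water_comparison <- function(x, ...) {
  cat("excess-water comparison (A / B):\n")
  for (nm in names(x$verdicts)) cat("  ", nm, ":", x$verdicts[nm], "\n")
  agg <- stats::aggregate(ratio ~ process, data = x$tau_ratios, FUN = stats::median)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("   process %d median tau ratio: %.3g\n",
                agg$process[i], agg$ratio[i]))
  cat("  carbonyl ratio trends: A", x$carbonyl_directions["a"],
      "/ B", x$carbonyl_directions["b"], "\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` plus tidy CSV tables (phase series, relaxation map,
#' water fractions, carbonyl series) under `dir`.
#'
#' @param report a `"study_report"`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$phase_series))
    utils::write.csv(report$phase_series,
                     file.path(dir, "phase_series.csv"), row.names = FALSE)
  if (!is.null(report$relaxation_map))
    utils::write.csv(report$relaxation_map$data,
                     file.path(dir, "relaxation_map.csv"), row.names = FALSE)
  if (!is.null(report$phi_series))
    utils::write.csv(report$phi_series,
                     file.path(dir, "water_fractions.csv"), row.names = FALSE)
  if (!is.null(report$carbonyl_series))
    utils::write.csv(report$carbonyl_series,
                     file.path(dir, "carbonyl_ratio.csv"), row.names = FALSE)
  summary <- list(
    transition_window_saxs = report$transition_window_saxs,
    kinks = report$kinks,
    phi_discontinuity = report$phi_discontinuity,
    carbonyl_direction = report$carbonyl_direction,
    consensus = report$consensus,
    errors = report$errors)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(dir)
}
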