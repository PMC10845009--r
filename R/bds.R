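# Broadband dielectric spectroscopy: Havriliak-Negami models, loss-tangent
# analysis, spectrum fitting and relaxation maps.

# Vacuum permittivity in F/m.
EPS_VACUUM <- 8.8541878128e-12

#' Define one Havriliak-Negami relaxation process
#'
#' The complex-permittivity contribution of one process is
#' `delta_eps / (1 + (i*omega*tau_hn)^alpha)^gamma` with symmetric
#' broadening `alpha` and asymmetric broadening `gamma`
#' (0 < alpha, alpha*gamma <= 1). `alpha = gamma = 1` is the Debye case.
#'
#' @param delta_eps relaxation strength (> 0, dimensionless).
#' @param tau_hn characteristic relaxation time in seconds (> 0).
#' @param alpha,gamma broadening exponents.
#' @return An object of class `"hn_process"`.
#' @export
hn_process <- function(delta_eps, tau_hn, alpha = 1, gamma = 1) {
  if (delta_eps <= 0) stop_mesokit("delta_eps must be > 0", "mesokit_validation")
  if (tau_hn <= 0) stop_mesokit("tau_hn must be > 0", "mesokit_validation")
  if (alpha <= 0 || alpha > 1 || alpha * gamma <= 0 || alpha * gamma > 1)
    stop_mesokit("need 0 < alpha <= 1 and 0 < alpha*gamma <= 1",
                 "mesokit_validation")
  structure(list(delta_eps = delta_eps, tau_hn = tau_hn,
                 alpha = alpha, gamma = gamma),
            class = "hn_process")
}

#' Assemble a dielectric model from processes plus dc conductivity
#'
#' @param processes list of [hn_process()] objects (may be empty); stored
#'   ordered by decreasing `tau_hn` so that process 1 is the slowest.
#' @param eps_inf high-frequency permittivity limit (>= 1).
#' @param sigma dc conductivity in S/m (>= 0); contributes
#'   `sigma / (omega * eps_f)` to the imaginary part only.
#' @return An object of class `"dielectric_model"`.
#' @export
dielectric_model <- function(processes = list(), eps_inf = 2, sigma = 0) {
  if (inherits(processes, "hn_process")) processes <- list(processes)
  stopifnot(all(vapply(processes, inherits, logical(1), "hn_process")))
  if (eps_inf < 1) stop_mesokit("eps_inf must be >= 1", "mesokit_validation")
  if (sigma < 0) stop_mesokit("sigma must be >= 0", "mesokit_validation")
  if (length(processes)) {
    taus <- vapply(processes, `[[`, numeric(1), "tau_hn")
    processes <- processes[order(taus, decreasing = TRUE)]
  }
  structure(list(processes = processes, eps_inf = eps_inf, sigma = sigma,
                 eps_f = EPS_VACUUM),
            class = "dielectric_model")
}

#' Construct a dielectric spectrum
#'
#' @param frequency frequency grid in Hz, strictly increasing.
#' @param eps_real,eps_imag real and imaginary parts of the complex
#'   permittivity, same length as `frequency`.
#' @param temperature,water_wt metadata (deg C, wt%).
#' @return An object of class `"dielectric_spectrum"`.
#' @export
dielectric_spectrum <- function(frequency, eps_real, eps_imag,
                                temperature = NA_real_, water_wt = NA_real_) {
  frequency <- as.numeric(frequency)
  if (!is_strictly_increasing(frequency) || any(frequency <= 0))
    stop_mesokit("frequency grid must be positive and strictly increasing",
                 "mesokit_validation")
  if (length(eps_real) != length(frequency) ||
      length(eps_imag) != length(frequency))
    stop_mesokit("grid lengths differ", "mesokit_validation")
  if (any(eps_imag < 0))
    stop_mesokit("eps_imag must be nonnegative", "mesokit_validation")
  if (any(eps_real < 1))
    warning("eps_real below 1: check data scaling")
  structure(list(frequency = frequency, eps_real = as.numeric(eps_real),
                 eps_imag = as.numeric(eps_imag),
                 temperature = as.numeric(temperature),
                 water_wt = as.numeric(water_wt)),
            class = "dielectric_spectrum")
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("dielectric spectrum: %d points, f in [%.3g, %.3g] Hz, T = %s C\n",
              length(x$frequency), min(x$frequency), max(x$frequency),
              format(x$temperature)))
  invisible(x)
}

#' Evaluate a dielectric model on a frequency grid
#'
#' Computes `eps*(omega) = eps_inf + sum_k delta_eps_k /
#' (1 + (i*omega*tau_k)^alpha_k)^gamma_k` with the principal branch of the
#' complex power, then adds the conductivity term `sigma/(omega*eps_f)` to
#' the imaginary part only.
#'
#' @param model a [dielectric_model()].
#' @param frequency positive frequencies in Hz, strictly increasing.
#' @param temperature,water_wt metadata copied onto the result.
#' @return A `"dielectric_spectrum"`.
#' @export
evaluate_model <- function(model, frequency, temperature = NA_real_,
                           water_wt = NA_real_) {
  stopifnot(inherits(model, "dielectric_model"))
  frequency <- as.numeric(frequency)
  if (any(frequency <= 0))
    stop_mesokit("frequencies must be positive", "mesokit_validation")
  omega <- 2 * pi * frequency
  eps <- rep(complex(real = model$eps_inf), length(omega))
  for (p in model$processes) {
    eps <- eps + p$delta_eps /
      (1 + (1i * omega * p$tau_hn)^p$alpha)^p$gamma
  }
  dielectric_spectrum(frequency, Re(eps),
                      -Im(eps) + model$sigma / (omega * model$eps_f),
                      temperature, water_wt)
}

#' Loss tangent of a dielectric spectrum
#'
#' @param spectrum a `"dielectric_spectrum"`.
#' @return Numeric vector `eps_imag / eps_real`.
#' @export
tan_delta <- function(spectrum) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  bad <- which(spectrum$eps_real == 0)
  if (length(bad))
    stop_mesokit(paste0("eps_real is zero at frequency ",
                        format(spectrum$frequency[bad[1]], digits = 6), " Hz"),
                 "mesokit_division")
  spectrum$eps_imag / spectrum$eps_real
}

#' Loss-tangent peak position of a Debye process
#'
#' For a single Debye process with no dc conductivity the loss tangent
#' peaks at `omega * tau = sqrt(1 + delta_eps / eps_h)`, i.e. above the
#' dielectric-loss peak (which sits at `omega * tau = 1`).
#'
#' @param delta_eps relaxation strength (>= 0).
#' @param eps_h high-frequency permittivity limit (> 0).
#' @return The dimensionless `omega * tau` at the tan-delta maximum.
#' @export
debye_tan_delta_peak <- function(delta_eps, eps_h) {
  if (eps_h <= 0) stop_mesokit("eps_h must be > 0", "mesokit_validation")
  if (delta_eps < 0) stop_mesokit("delta_eps must be >= 0", "mesokit_validation")
  sqrt(1 + delta_eps / eps_h)
}

#' Relaxation time at maximum loss for an HN process
#'
#' Converts the Havriliak-Negami characteristic time to the relaxation time
#' of the loss-peak maximum via the closed form
#' `tau_max = tau_hn * (sin(pi*alpha*gamma/(2+2*gamma)) /
#' sin(pi*alpha/(2+2*gamma)))^(1/alpha)`; the Debye case returns `tau_hn`.
#'
#' @param process an [hn_process()].
#' @return `tau_max` in seconds.
#' @export
tau_max_from_hn <- function(process) {
  stopifnot(inherits(process, "hn_process"))
  process$tau_hn * hn_peak_shift(process$alpha, process$gamma)
}

# tau_max / tau_hn for given HN exponents (<= 1, equality in symmetric cases).
hn_peak_shift <- function(alpha, gamma) {
  (sin(pi * alpha * gamma / (2 * (1 + gamma))) /
     sin(pi * alpha / (2 * (1 + gamma))))^(1 / alpha)
}

# --- parameter packing for fits ------------------------------------------
# Layout: per process (log10 delta_eps, log10 tau_hn, alpha, gamma), then
# eps_inf, log10 sigma.
pack_model <- function(model) {
  pr <- model$processes
  c(unlist(lapply(pr, function(p) c(log10(p$delta_eps), log10(p$tau_hn)))),
    unlist(lapply(pr, function(p) c(p$alpha, p$gamma))),
    model$eps_inf, log10(max(model$sigma, 1e-16)))
}

unpack_model <- function(par, n_proc) {
  if (n_proc > 0) {
    dt <- matrix(par[seq_len(2 * n_proc)], nrow = 2)
    ag <- matrix(par[2 * n_proc + seq_len(2 * n_proc)], nrow = 2)
    procs <- lapply(seq_len(n_proc), function(k)
      structure(list(delta_eps = 10^dt[1, k], tau_hn = 10^dt[2, k],
                     alpha = ag[1, k], gamma = ag[2, k]),
                class = "hn_process"))
  } else procs <- list()
  eps_inf <- par[4 * n_proc + 1L]
  sigma <- 10^par[4 * n_proc + 2L]
  structure(list(processes = procs, eps_inf = eps_inf, sigma = sigma,
                 eps_f = EPS_VACUUM),
            class = "dielectric_model")
}

eval_raw <- function(par, n_proc, omega) {
  eps <- rep(complex(real = par[4 * n_proc + 1L]), length(omega))
  for (k in seq_len(n_proc)) {
    deps <- 10^par[2 * k - 1L]; tau <- 10^par[2 * k]
    a <- par[2 * n_proc + 2 * k - 1L]; g <- par[2 * n_proc + 2 * k]
    eps <- eps + deps / (1 + (1i * omega * tau)^a)^g
  }
  list(re = Re(eps), im = -Im(eps) + 10^par[4 * n_proc + 2L] / (omega * EPS_VACUUM))
}

default_bounds <- function(n_proc) {
  lower <- c(rep(c(-2, -9), n_proc), rep(c(0.2, 0.2), n_proc), 1, -16)
  upper <- c(rep(c(3, 4), n_proc), rep(c(1, 1), n_proc), 50, -6)
  list(lower = lower, upper = upper)
}

# Number of resolvable local maxima of the conductivity-corrected loss;
# used to pick the anchor end of a temperature series.
# Local maxima of the smoothed log loss whose topographic prominence
# exceeds min_prominence decades, ordered by height. Detection runs on the
# raw loss: the monotone dc-conductivity rise cannot form local maxima,
# while subtracting an estimated conductivity creates cancellation
# artifacts near the low-frequency window edge.
prominent_loss_maxima <- function(spectrum, min_prominence = 0.05) {
  prominent_log_maxima(spectrum$eps_imag, min_prominence)
}

prominent_log_maxima <- function(v, min_prominence = 0.05) {
  y <- moving_average(log10(pmax(v, 1e-12)), 5L)
  n <- length(y)
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(loc)) return(integer(0))
  prom <- vapply(loc, function(i) {
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left > y[i])
    lo_l <- if (length(higher_l)) min(y[(max(higher_l) + 1L):(i - 1L)]) else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right > y[i])
    lo_r <- if (length(higher_r)) min(y[i + seq_len(min(higher_r) - 1L)]) else min(right)
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  loc[keep][order(y[loc[keep]], decreasing = TRUE)]
}

count_loss_peaks <- function(spectrum, min_prominence = 0.1) {
  length(prominent_loss_maxima(spectrum, min_prominence))
}

# Data-driven starting points: tau from local maxima of the
# conductivity-corrected loss, delta_eps from the dispersion steps of
# eps_real between neighbouring loss peaks. When fewer maxima are resolved
# than processes requested, the hidden process(es) may sit beyond either
# window edge, so one structural variant is built per way of distributing
# the extras between the slow and fast ends.
initial_guesses <- function(spectrum, n_proc) {
  f <- spectrum$frequency; re <- spectrum$eps_real; im <- spectrum$eps_imag
  sig0 <- max(im[1] * 2 * pi * f[1] * EPS_VACUUM, 1e-15)
  if (n_proc == 0L)
    return(list(c(max(min(re), 1), log10(sig0))))
  # peak positions from both the loss and the loss tangent: a slow process
  # whose loss peak sits below the window edge can still peak in tan delta,
  # which is shifted up by the (1 + delta_eps/eps_h)^(1/2) factor
  extend_sets <- function(taus) {
    n_extra <- n_proc - length(taus)
    if (n_extra <= 0) return(list(taus))
    lapply(0:n_extra, function(j) {
      slow <- if (j > 0) max(taus) * 30^seq_len(j) else numeric(0)
      fast <- if (n_extra - j > 0) min(taus) / 30^seq_len(n_extra - j)
              else numeric(0)
      sort(c(slow, taus, fast), decreasing = TRUE)
    })
  }
  taus_from <- function(loc) {
    if (!length(loc)) return(NULL)
    sort(1 / (2 * pi * f[loc[seq_len(min(n_proc, length(loc)))]]),
         decreasing = TRUE)
  }
  loc_loss <- prominent_loss_maxima(spectrum)
  loc_tand <- if (all(re > 0)) prominent_log_maxima(im / re) else integer(0)

  # prominence-ranked sets per representation, end-extended when short
  tau_sets <- list()
  for (ts in Filter(Negate(is.null),
                    list(taus_from(loc_loss), taus_from(loc_tand))))
    tau_sets <- c(tau_sets, extend_sets(ts))

  # plus n_proc-subsets of the merged candidate pool (clustered to a
  # quarter decade): covers processes seen in only one representation
  pool <- c(1 / (2 * pi * f[loc_loss]), 1 / (2 * pi * f[loc_tand]))
  if (length(pool)) {
    lp <- sort(log10(pool))
    groups <- cumsum(c(TRUE, diff(lp) > 0.25))
    cand_taus <- sort(10^vapply(split(lp, groups), mean, numeric(1)),
                      decreasing = TRUE)
    if (length(cand_taus) > n_proc) {
      combos <- utils::combn(length(cand_taus), n_proc, simplify = FALSE)
      if (length(combos) > 12L) combos <- combos[seq_len(12L)]
      tau_sets <- c(tau_sets, lapply(combos, function(ix)
        sort(cand_taus[ix], decreasing = TRUE)))
    } else {
      tau_sets <- c(tau_sets, extend_sets(unname(cand_taus)))
    }
  }
  if (!length(tau_sets))
    tau_sets <- extend_sets(1 / (2 * pi * stats::median(f)))
  tau_sets <- unique(tau_sets)

  lapply(tau_sets, function(ts) {
    fpk <- sort(1 / (2 * pi * ts))
    cuts <- c(min(f), sqrt(fpk[-1] * fpk[-length(fpk)]), max(f))
    epl <- stats::approx(log10(f), re, xout = log10(cuts), rule = 2)$y
    deps <- pmax(epl[-length(epl)] - epl[-1], 0.1)
    c(rbind(log10(deps), log10(ts)), rep(0.9, 2 * n_proc),
      max(min(re), 1), log10(sig0))
  })
}

#' Fit a dielectric spectrum with a sum of HN processes plus conductivity
#'
#' Least squares on relative residuals in the chosen representation
#' (uniform weight per point on the log-spaced frequency grid), solved with
#' Levenberg-Marquardt under box constraints. Starting points are
#' data-driven (relaxation times from local maxima of the
#' conductivity-corrected loss, strengths from the dispersion steps of the
#' real part); additional randomized starts perturb them, and the
#' best-residual solution wins. When `init` is supplied (e.g. the previous
#' temperature of a series) it becomes the first start, and `tether > 0`
#' adds a mild quadratic pull of the slowly-varying parameters (strengths,
#' shape exponents, eps_inf, conductivity - not the relaxation times)
#' toward it, which stabilises processes whose loss peak has drifted
#' outside the measured window.
#'
#' @param spectrum a `"dielectric_spectrum"` spanning at least 3 decades.
#' @param n_processes number of HN processes, 0 to 4.
#' @param representation fit the loss tangent (`"tan_delta"`, default) or
#'   the dielectric loss (`"eps_imag"`).
#' @param init optional `"dielectric_model"` or packed parameter vector used
#'   as the first start.
#' @param tether nonnegative weight of the continuation penalty (0 = off).
#' @param n_starts number of randomized starts (>= 1).
#' @param seed RNG seed for the randomized starts.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `"dielectric_fit"`: `model`, `tau_max`
#'   (seconds, decreasing), `representation`, `residual` (rms relative),
#'   `se` (per-parameter standard errors where estimable), `converged`,
#'   and `flags` (character; e.g. under-resolved processes).
#' @export
fit_spectrum <- function(spectrum, n_processes = 3L,
                         representation = c("tan_delta", "eps_imag"),
                         init = NULL, tether = 0, n_starts = 8L, seed = NULL,
                         maxiter = 400L) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  representation <- match.arg(representation)
  n_proc <- as.integer(n_processes)
  if (n_proc < 0L || n_proc > 4L)
    stop_mesokit("n_processes must be between 0 and 4", "mesokit_validation")
  f <- spectrum$frequency
  if (log10(max(f) / min(f)) < 3)
    stop_mesokit("spectrum must span at least 3 decades", "mesokit_validation")
  omega <- 2 * pi * f
  target <- switch(representation,
                   tan_delta = tan_delta(spectrum),
                   eps_imag = spectrum$eps_imag)
  target[target == 0] <- .Machine$double.eps

  bounds <- default_bounds(n_proc)
  npar <- length(bounds$lower)
  tether_idx <- if (n_proc > 0)
    c(seq_len(2 * n_proc)[seq_len(2 * n_proc) %% 2 == 1L],  # log10 delta_eps
      2 * n_proc + seq_len(2 * n_proc),                     # alpha, gamma
      4 * n_proc + 1L, 4 * n_proc + 2L)                     # eps_inf, sigma
  else c(1L, 2L)

  p_init <- NULL
  if (!is.null(init)) {
    p_init <- if (inherits(init, "dielectric_model")) pack_model(init) else as.numeric(init)
    if (length(p_init) != npar)
      stop_mesokit("init has the wrong number of parameters", "mesokit_validation")
    p_init <- pmin(pmax(p_init, bounds$lower), bounds$upper)
  }
  p_data <- lapply(initial_guesses(spectrum, n_proc), function(p)
    pmin(pmax(p, bounds$lower), bounds$upper))

  residual_fn <- function(p) {
    m <- eval_raw(p, n_proc, omega)
    r <- switch(representation,
                tan_delta = (m$im / m$re) / target - 1,
                eps_imag = m$im / target - 1)
    if (tether > 0 && !is.null(p_init))
      r <- c(r, tether * (p[tether_idx] - p_init[tether_idx]) /
               sqrt(length(tether_idx)))
    r
  }

  run_start <- function(p0) {
    # Levenberg-Marquardt with restart polishing: a cold restart from the
    # converged point escapes the occasional premature stall.
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, bounds$lower, bounds$upper, fn = residual_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    rss <- sum(fit$fvec^2)
    for (pol in 1:3) {
      fit2 <- tryCatch(
        minpack.lm::nls.lm(fit$par, bounds$lower, bounds$upper,
                           fn = residual_fn,
                           control = minpack.lm::nls.lm.control(maxiter = maxiter)),
        error = function(e) NULL)
      if (is.null(fit2)) break
      rss2 <- sum(fit2$fvec^2)
      if (rss2 >= rss * (1 - 1e-8)) { if (rss2 < rss) { fit <- fit2; rss <- rss2 }; break }
      fit <- fit2; rss <- rss2
    }
    list(fit = fit, rss = rss)
  }

  best <- NULL
  with_seed(seed, {
    starts <- list()
    if (!is.null(p_init)) starts <- c(starts, list(p_init))
    starts <- c(starts, p_data)
    while (length(starts) < max(n_starts, length(starts))) {
      base <- if (!is.null(p_init)) p_init
              else p_data[[sample.int(length(p_data), 1L)]]
      jit <- base
      if (n_proc > 0) {
        jit[seq_len(2 * n_proc)] <- jit[seq_len(2 * n_proc)] +
          stats::rnorm(2 * n_proc, 0, 0.3)
        jit[2 * n_proc + seq_len(2 * n_proc)] <-
          pmin(pmax(jit[2 * n_proc + seq_len(2 * n_proc)] +
                      stats::rnorm(2 * n_proc, 0, 0.05), 0.3), 1)
      }
      starts <- c(starts, list(pmin(pmax(jit, bounds$lower), bounds$upper)))
    }
    for (p0 in starts) {
      res <- run_start(p0)
      if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
    }
  })
  if (is.null(best))
    stop_mesokit("fit failed: no start converged", "mesokit_fit_failed")

  fit <- best$fit
  par <- fit$par
  model <- unpack_model(par, n_proc)
  o <- if (n_proc > 0)
    order(vapply(model$processes, `[[`, numeric(1), "tau_hn"), decreasing = TRUE)
  else integer(0)
  model$processes <- model$processes[o]
  taumax <- vapply(model$processes, tau_max_from_hn, numeric(1))

  se <- rep(NA_real_, npar)
  cov <- tryCatch({
    dof <- max(length(fit$fvec) - npar, 1L)
    s2 <- sum(fit$fvec^2) / dof
    s2 * solve(fit$hessian)
  }, error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov); d[d < 0] <- NA_real_
    se <- sqrt(d)
  }

  flags <- character(0)
  if (n_proc >= 2L) {
    lt <- log10(vapply(model$processes, `[[`, numeric(1), "tau_hn"))
    if (any(abs(diff(lt)) < 0.3))
      flags <- c(flags, "processes closer than 0.3 decades: may be under-resolved")
  }

  structure(list(model = model, tau_max = taumax,
                 representation = representation,
                 residual = sqrt(mean((residual_fn(par)[seq_along(omega)])^2)),
                 par = par, se = se,
                 converged = fit$info %in% 1:4, flags = flags),
            class = "dielectric_fit")
}

#' @export
print.dielectric_fit <- function(x, ...) {
  cat(sprintf("HN fit (%s): %d process(es), rms rel. residual %.3g\n",
              x$representation, length(x$model$processes), x$residual))
  for (k in seq_along(x$model$processes)) {
    p <- x$model$processes[[k]]
    cat(sprintf("  process %d: tau_max = %.3g s, delta_eps = %.3g, alpha = %.2f, gamma = %.2f\n",
                k, x$tau_max[k], p$delta_eps, p$alpha, p$gamma))
  }
  cat(sprintf("  eps_inf = %.3g, sigma = %.3g S/m\n",
              x$model$eps_inf, x$model$sigma))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Build a relaxation map from a dielectric temperature series
#'
#' Fits every spectrum of the series and collects per-process relaxation
#' times at maximum loss. Fitting starts at the temperature where the
#' processes are fastest (hottest, by default), where every loss peak is
#' most likely to sit inside the measured window, and continues to the
#' neighbouring temperatures using each converged fit as the next start
#' with a mild continuation tether (see [fit_spectrum()]). Process identity
#' is tracked by relaxation-time ordering; when the nearest-neighbour
#' matching between consecutive temperatures disagrees with that ordering
#' the point is flagged as a possible crossing.
#'
#' @param spectra list of `"dielectric_spectrum"` objects at >= 4 distinct
#'   temperatures.
#' @param n_processes,representation,n_starts,seed,maxiter see
#'   [fit_spectrum()].
#' @param tether continuation-penalty weight for the chained fits.
#' @param anchor `"auto"` (default) starts at whichever end of the series
#'   shows more resolvable loss peaks (ties go to the hot end); `"hot"` or
#'   `"cold"` force the choice. The anchor end is fitted first with the
#'   full multi-start search.
#' @return An object of class `"relaxation_map"`: `data` (data frame with
#'   temperature, process, tau_max_s, delta_eps, alpha, gamma, sigma,
#'   eps_inf, residual, flagged), and `fits` (per-temperature
#'   `"dielectric_fit"` objects, ordered by temperature).
#' @export
build_relaxation_map <- function(spectra, n_processes = 3L,
                                 representation = "tan_delta",
                                 tether = 2, n_starts = 8L, seed = NULL,
                                 maxiter = 400L,
                                 anchor = c("auto", "hot", "cold")) {
  anchor <- match.arg(anchor)
  temps <- vapply(spectra, `[[`, numeric(1), "temperature")
  if (length(spectra) < 4L || length(unique(temps)) < 4L)
    stop_mesokit("need a series of >= 4 distinct temperatures",
                 "mesokit_validation")
  o <- order(temps)
  spectra <- spectra[o]; temps <- temps[o]
  n <- length(spectra)
  if (anchor == "auto") {
    anchor <- if (count_loss_peaks(spectra[[1L]]) >
                  count_loss_peaks(spectra[[n]])) "cold" else "hot"
  }
  idx <- if (anchor == "hot") rev(seq_len(n)) else seq_len(n)

  fits <- vector("list", n)
  rows <- vector("list", n)
  prev_par <- NULL
  prev_tau <- NULL
  with_seed(seed, {
    for (i in idx) {
      fit <- fit_spectrum(spectra[[i]], n_processes, representation,
                          init = prev_par,
                          tether = if (is.null(prev_par)) 0 else tether,
                          n_starts = if (is.null(prev_par)) n_starts else 3L,
                          seed = NULL, maxiter = maxiter)
      fits[[i]] <- fit
      prev_par <- fit$par

      flagged <- FALSE
      if (!is.null(prev_tau) && length(fit$tau_max) == length(prev_tau)) {
        # nearest-neighbour matching in log tau vs. plain ordering
        lt <- log10(fit$tau_max); lp <- log10(prev_tau)
        nearest <- vapply(lt, function(v) which.min(abs(lp - v)), integer(1))
        flagged <- !identical(nearest, seq_along(lt)) || anyDuplicated(nearest) > 0
      }
      prev_tau <- fit$tau_max

      pr <- fit$model$processes
      rows[[i]] <- data.frame(
        temperature = temps[i],
        process = seq_along(pr),
        tau_max_s = fit$tau_max,
        delta_eps = vapply(pr, `[[`, numeric(1), "delta_eps"),
        alpha = vapply(pr, `[[`, numeric(1), "alpha"),
        gamma = vapply(pr, `[[`, numeric(1), "gamma"),
        sigma = fit$model$sigma,
        eps_inf = fit$model$eps_inf,
        residual = fit$residual,
        flagged = flagged)
    }
  })
  data <- do.call(rbind, rows[order(temps)])
  rownames(data) <- NULL
  structure(list(data = data, fits = fits), class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  temps <- unique(x$data$temperature)
  cat("relaxation map:", length(temps), "temperatures,",
      max(x$data$process), "process(es)\n")
  print(utils::head(x$data[, c("temperature", "process", "tau_max_s")], 12))
  if (nrow(x$data) > 12) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.relaxation_map <- function(x, ...) x$data

#' Detect the phase-transition kink in a relaxation map
#'
#' Tests log10(tau_max) against inverse absolute temperature (Arrhenius
#' coordinates) for a single breakpoint using [detect_breakpoint()]: one
#' straight line versus two joined lines, decided by BIC.
#'
#' @param map a `"relaxation_map"`.
#' @param process which process to test (default 1, the slowest).
#' @param min_bic_improvement passed to [detect_breakpoint()].
#' @return A list with `kink_temperature` (deg C, or `NA` when a single
#'   Arrhenius line suffices) and the underlying `"breakpoint_fit"`.
#' @export
detect_kink <- function(map, process = 1L, min_bic_improvement = 0) {
  stopifnot(inherits(map, "relaxation_map"))
  d <- map$data[map$data$process == process, ]
  if (nrow(d) < 6L)
    stop_mesokit("need >= 6 temperatures for the kink test", "mesokit_validation")
  x <- 1 / (d$temperature + 273.15)
  y <- log10(d$tau_max_s)
  bp <- detect_breakpoint(x, y, min_bic_improvement = min_bic_improvement)
  kt <- if (is.na(bp$breakpoint)) NA_real_ else 1 / bp$breakpoint - 273.15
  list(kink_temperature = kt, fit = bp)
}
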