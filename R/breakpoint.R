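#' Detect a single breakpoint in a noisy linear trend
#'
#' Fits a continuous two-segment ("hinge") linear model with the breakpoint
#' scanned over interior sample points, and compares it against a single
#' straight line by BIC. This one routine backs both the Arrhenius-map kink
#' test of the dielectric module and the band-centre discontinuity test of
#' the FTIR module, so the two modalities apply an identical criterion.
#'
#' @param x,y numeric vectors of equal length (at least `2 * min_segment`
#'   finite points). `x` need not be sorted.
#' @param min_segment minimum number of points required on each side of a
#'   candidate breakpoint (the breakpoint sample is counted in both).
#' @param min_bic_improvement how much lower (in BIC units) the two-segment
#'   model must score before a breakpoint is reported. 0 means any BIC win.
#' @return A list of class `"breakpoint_fit"` with elements `breakpoint`
#'   (the x value, or `NA` when a single line suffices), `delta_bic`
#'   (BIC(line) - BIC(hinge), positive favours the hinge), `slopes`
#'   (pre/post-break slopes of the hinge fit), `sse_line`, `sse_hinge`.
#' @examples
#' x <- 1:12
#' y <- c(1:6, 6 + 3 * (1:6)) + 0  # slope change at x = 6
#' detect_breakpoint(x, y)$breakpoint
#' @export
detect_breakpoint <- function(x, y, min_segment = 3L, min_bic_improvement = 0) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  out <- list(breakpoint = NA_real_, delta_bic = NA_real_,
              slopes = c(NA_real_, NA_real_),
              sse_line = NA_real_, sse_hinge = NA_real_)
  class(out) <- "breakpoint_fit"
  if (n < 2L * min_segment) return(out)

  fit_line <- stats::lm.fit(cbind(1, x), y)
  sse1 <- sum(fit_line$residuals^2)
  # SSE floor keeps the log finite for noiseless inputs; both models share it
  # so the parameter penalty alone decides degenerate cases.
  floor_sse <- max(1e-12 * sum(y^2), 1e-300)
  bic <- function(sse, k) n * log(max(sse, floor_sse) / n) + k * log(n)

  cand <- seq.int(min_segment, n - min_segment + 1L)
  best <- NULL
  for (k in cand) {
    hinge <- pmax(x - x[k], 0)
    fit2 <- stats::lm.fit(cbind(1, x, hinge), y)
    sse2 <- sum(fit2$residuals^2)
    if (is.null(best) || sse2 < best$sse) {
      best <- list(k = k, sse = sse2, coef = fit2$coefficients)
    }
  }
  # 2 coefficients for the line; 3 plus the scanned breakpoint for the hinge.
  delta <- bic(sse1, 2L) - bic(best$sse, 4L)
  out$delta_bic <- delta
  out$sse_line <- sse1
  out$sse_hinge <- best$sse
  if (is.finite(delta) && delta > min_bic_improvement) {
    out$breakpoint <- x[best$k]
    out$slopes <- c(best$coef[2L], best$coef[2L] + best$coef[3L])
  }
  out
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat("breakpoint: none (single line preferred, delta BIC =",
        format(x$delta_bic, digits = 3), ")\n")
  } else {
    cat("breakpoint at x =", format(x$breakpoint, digits = 6),
        "; slopes", format(x$slopes[1], digits = 3), "->",
        format(x$slopes[2], digits = 3),
        "; delta BIC =", format(x$delta_bic, digits = 3), "\n")
  }
  invisible(x)
}
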