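# Internal helpers shared across modules.

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Piecewise-linear interpolation of y over 1/T(K); `nodes` is a 2-column
# matrix (T in deg C, y). Used for Arrhenius-branch schedules.
interp_inv_kelvin <- function(nodes, temperature) {
  x <- 1 / (nodes[, 1] + 273.15)
  stats::approx(x, nodes[, 2], xout = 1 / (temperature + 273.15), rule = 2)$y
}

# Piecewise-linear interpolation on the temperature axis itself.
interp_linear <- function(nodes, temperature) {
  stats::approx(nodes[, 1], nodes[, 2], xout = temperature, rule = 2)$y
}

stop_mesokit <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mesokit_error")))
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

# Centered moving average; endpoints keep the raw values.
moving_average <- function(y, window) {
  window <- as.integer(window)
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(y, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- y[is.na(sm)]
  sm
}
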