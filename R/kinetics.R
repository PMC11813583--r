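# Michaelis-Menten degradation at fixed cell count admits an implicit
# solution: da/dt = -(E N / V) a/(a + K_M) integrates to
#   a + K_M ln a = a0 + K_M ln a0 - (E N / V) t.
# More generally, for any time course N(t), the "degradation work"
# w(t) = (E/V) * integral_0^t N(s) ds satisfies g(a(t)) = g(a0) - w(t) with
# g(a) = a + K_M ln a. Both the deterministic simulator and the stochastic
# engine reduce antibiotic updates to inverting g, done here by Newton
# iteration in u = ln a, where the objective e^u + K_M u is convex and
# increasing, so iteration from u0 = ln a0 converges monotonically.

mm_potential <- function(a, K_M) a + K_M * log(a)

# Solve g(a) = g(a0) - w for a in (0, a0]; w >= 0 is the accumulated
# degradation work in concentration units. Vectorised over a0 and w.
mm_invert <- function(a0, w, K_M, rel_tol = 1e-12) {
  stopifnot(all(a0 >= 0), all(w >= 0))
  n <- max(length(a0), length(w))
  a0 <- rep_len(a0, n); w <- rep_len(w, n)
  out <- a0
  todo <- a0 > 0 & w > 0
  if (!any(todo)) return(out)
  target <- mm_potential(a0[todo], K_M) - w[todo]
  # degradation work beyond representable concentrations: a underflows to 0
  floor_u <- log(.Machine$double.xmin) / 2
  dead <- !is.finite(target) | target < K_M * floor_u
  if (any(dead)) {
    idx <- which(todo)
    out[idx[dead]] <- 0
    todo[idx[dead]] <- FALSE
    target <- target[!dead]
    if (!any(todo)) return(out)
  }
  u <- log(a0[todo])
  for (iter in 1:200) {
    f <- exp(u) + K_M * u - target
    du <- f / (exp(u) + K_M)
    u <- u - du
    if (all(abs(du) <= rel_tol * pmax(1, abs(u)))) break
  }
  out[todo] <- exp(u)
  out
}

#' Advance the antibiotic concentration over a fixed interval
#'
#' Exact update of the Michaelis-Menten degradation law over a time interval
#' during which the live-cell count is constant: returns the `a` solving
#' `a + K_M log(a) = a0 + K_M log(a0) - E * n_cells * dt / V`. This is the
#' antibiotic half of the hybrid stochastic engine, where the population is
#' piecewise constant between birth/death events.
#'
#' @param params a [model_params()] object.
#' @param n_cells live cell count held fixed over the interval.
#' @param a0 concentration at the start of the interval, ug/ml.
#' @param dt interval length, minutes (non-negative).
#' @param volume sub-volume, ml.
#' @return Concentration at the end of the interval, in `(0, a0]`
#'   (equal to `a0` when `dt = 0`, `n_cells = 0`, or `enzyme_rate = 0`).
#' @export
#' @examples
#' p <- model_params()
#' advance_antibiotic(p, n_cells = 10, a0 = 15, dt = 9.184, volume = 1e-7)
advance_antibiotic <- function(params, n_cells, a0, dt, volume) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(a0) || a0 < 0 || !is.finite(a0))
    stop("'a0' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(dt) || dt < 0 || !is.finite(dt))
    stop("'dt' must be finite and non-negative", call. = FALSE)
  if (n_cells < 0) stop("'n_cells' must be non-negative", call. = FALSE)
  if (volume <= 0) stop("'volume' must be positive", call. = FALSE)
  w <- params$enzyme_rate * n_cells * dt / volume
  mm_invert(a0, w, params$K_M)
}

#' Time for the antibiotic to fall to the threshold at fixed cell count
#'
#' Closed-form inversion of the degradation law at constant `n_cells`:
#' the time at which `a(t)` first reaches the threshold `a_th`,
#' `t = V * (a0 - a_th + K_M log(a0/a_th)) / (E * n_cells)`.
#' This is the degradation timescale in the "race for survival" between
#' killing and detoxification, and the event-location primitive of the
#' stochastic engine.
#'
#' @inheritParams advance_antibiotic
#' @param a0 starting concentration, must be at or above the threshold.
#' @return Crossing time in minutes; `Inf` when `n_cells = 0` or
#'   `enzyme_rate = 0` (no degradation), `0` when `a0 = a_th`.
#' @export
#' @examples
#' antibiotic_crossing_time(model_params(), n_cells = 10, a0 = 15,
#'                          volume = 1e-7)
antibiotic_crossing_time <- function(params, n_cells, a0, volume) {
  stopifnot(inherits(params, "model_params"))
  if (any(a0 < params$a_th))
    stop("'a0' must be >= a_th (the concentration only decreases)",
         call. = FALSE)
  if (any(n_cells < 0)) stop("'n_cells' must be non-negative", call. = FALSE)
  if (volume <= 0) stop("'volume' must be positive", call. = FALSE)
  gap <- a0 - params$a_th + params$K_M * log(a0 / params$a_th)
  rate <- params$enzyme_rate * n_cells / volume
  ifelse(gap == 0, 0, ifelse(rate == 0, Inf, gap / rate))
}
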