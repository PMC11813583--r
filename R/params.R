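#' Kinetic parameters of the collective-defence model
#'
#' Bundles the rate constants of the toxin-degradation model: a population
#' grows at rate `mu` while the antibiotic concentration is at or below the
#' single-cell MIC threshold `a_th`, dies at rate `gamma` above it, and every
#' live cell degrades antibiotic with Michaelis-Menten kinetics of per-cell
#' capacity `enzyme_rate` (the product of enzyme copies per cell and the
#' per-enzyme maximal rate, so it carries units ug cell^-1 min^-1) and
#' Michaelis constant `K_M`.
#'
#' The defaults are the reference parameter set for beta-lactamase-producing
#' bacteria in a microfluidic-droplet setting used throughout the package's
#' examples: `mu` = 0.01 /min, `gamma` = 0.045 /min, `enzyme_rate` = 3.5e-8
#' ug cell^-1 min^-1, `K_M` = 6.7 ug/ml, `a_th` = 1 ug/ml.
#'
#' @param mu growth rate below threshold, per minute.
#' @param gamma death rate above threshold, per minute.
#' @param enzyme_rate combined per-cell degradation capacity E,
#'   ug cell^-1 min^-1. May be zero (no enzyme).
#' @param K_M Michaelis constant, ug/ml.
#' @param a_th threshold (single-cell MIC) antibiotic concentration, ug/ml.
#' @return An object of class `"model_params"`.
#' @export
#' @examples
#' p <- model_params()
#' critical_density(p, a_init = 15)
model_params <- function(mu = 0.01, gamma = 0.045, enzyme_rate = 3.5e-8,
                         K_M = 6.7, a_th = 1) {
  for (nm in c("mu", "gamma", "enzyme_rate", "K_M", "a_th")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  if (enzyme_rate < 0) stop("'enzyme_rate' must be non-negative", call. = FALSE)
  if (K_M <= 0) stop("'K_M' must be positive", call. = FALSE)
  if (a_th <= 0) stop("'a_th' must be positive", call. = FALSE)
  structure(list(mu = mu, gamma = gamma, enzyme_rate = enzyme_rate,
                 K_M = K_M, a_th = a_th),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Collective-defence model parameters:\n")
  cat(sprintf("  mu          = %g /min (growth below a_th)\n", x$mu))
  cat(sprintf("  gamma       = %g /min (death above a_th)\n", x$gamma))
  cat(sprintf("  enzyme_rate = %g ug cell^-1 min^-1 (E = b * r_max)\n",
              x$enzyme_rate))
  cat(sprintf("  K_M         = %g ug/ml\n", x$K_M))
  cat(sprintf("  a_th        = %g ug/ml (single-cell MIC)\n", x$a_th))
  invisible(x)
}

#' Initial condition of a single sub-volume
#'
#' @param n_init initial cell count (non-negative integer).
#' @param a_init initial antibiotic concentration, ug/ml.
#' @param volume sub-volume size; interpreted in `unit`.
#' @param unit volume unit: `"ml"`, `"pl"` (1e-9 ml) or `"um3"` (1e-12 ml).
#'   Stored internally in ml.
#' @return An object of class `"initial_condition"`.
#' @export
#' @examples
#' initial_condition(n_init = 9, a_init = 15, volume = 100, unit = "pl")
initial_condition <- function(n_init, a_init, volume, unit = "ml") {
  if (!is.numeric(n_init) || length(n_init) != 1L || !is.finite(n_init) ||
      n_init < 0 || n_init != round(n_init))
    stop("'n_init' must be a single non-negative integer", call. = FALSE)
  if (!is.numeric(a_init) || length(a_init) != 1L || !is.finite(a_init) ||
      a_init < 0)
    stop("'a_init' must be a single non-negative number", call. = FALSE)
  volume <- convert_volume(volume, unit)
  if (volume <= 0) stop("'volume' must be positive", call. = FALSE)
  structure(list(n_init = as.integer(round(n_init)), a_init = a_init,
                 volume = volume),
            class = "initial_condition")
}

#' Convert a volume to millilitres
#'
#' The package works internally in \{ml, min, ug, cells\}; picolitres and cubic
#' micrometres are accepted at the interface because experimental volumes
#' (droplets, pores, alveoli) are naturally quoted in those units.
#'
#' @param value volume value(s), non-negative.
#' @param unit `"ml"`, `"pl"` (1 pl = 1e-9 ml) or `"um3"` (1 um^3 = 1e-12 ml).
#' @return Volume in ml.
#' @export
#' @examples
#' convert_volume(100, "pl")   # 1e-7 ml
#' convert_volume(1e6, "um3")  # 1e-6 ml
convert_volume <- function(value, unit = c("ml", "pl", "um3")) {
  unit <- match.arg(unit)
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0))
    stop("volume must be finite and non-negative", call. = FALSE)
  value * switch(unit, ml = 1, pl = 1e-9, um3 = 1e-12)
}

# Derive the seed of replicate r (1-based) from a master seed. A fixed-odd
# multiplier LCG step keeps every replicate addressable by index alone, so
# estimates are reproducible independently of execution order.
replicate_seed <- function(master_seed, r) {
  (as.double(master_seed) + 1103515245 * as.double(r)) %% 2147483647
}
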