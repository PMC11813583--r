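#' Critical initial density for survival (the ecological phase boundary)
#'
#' A population exposed to antibiotic above the single-cell MIC survives and
#' regrows if and only if its initial density exceeds
#' \deqn{\rho^*(a_{init}) = \frac{\gamma}{E}\left[a_{init} - a_{th} +
#'   K_M \ln(a_{init}/a_{th})\right],}
#' the density at which total degradation capacity during the killing phase
#' exactly balances the antibiotic excess above threshold. The curve
#' \eqn{\rho^*(a_{init})} separates deterministic killing from survival and
#' encodes the inoculum effect: it is asymptotically linear in `a_init` when
#' `a_init >> K_M` and logarithmic when `a_init << K_M`.
#'
#' @param params a [model_params()] object.
#' @param a_init initial antibiotic concentration(s), ug/ml, at or above
#'   `a_th`.
#' @return Critical density in cells/ml (0 at `a_init = a_th`).
#' @export
#' @examples
#' p <- model_params()
#' critical_density(p, c(15, 35, 55, 75))  # 4.1e7, 7.4e7, 1.04e8, 1.3e8
critical_density <- function(params, a_init) {
  stopifnot(inherits(params, "model_params"))
  if (any(!is.finite(a_init)) || any(a_init < params$a_th))
    stop("'a_init' must be finite and >= a_th; the phase boundary is ",
         "undefined below the threshold", call. = FALSE)
  if (params$enzyme_rate == 0) return(rep(Inf, length(a_init)))
  (params$gamma / params$enzyme_rate) *
    (a_init - params$a_th + params$K_M * log(a_init / params$a_th))
}

#' Effective MIC of a population at a given density
#'
#' Inverts the phase boundary: the largest antibiotic concentration a bulk
#' population of density `rho` can survive. Because \eqn{\rho^*} is strictly
#' increasing and unbounded in `a_init`, the inverse exists and is found by
#' bracketed root finding (bracket doubled upward from `a_th` until it
#' contains the root).
#'
#' @inheritParams critical_density
#' @param rho population density, cells/ml (non-negative).
#' @return Concentration in ug/ml; `a_th` when `rho = 0`.
#' @export
#' @examples
#' effective_mic(model_params(), 5e7)  # ~19.9: the bulk survival threshold
effective_mic <- function(params, rho) {
  stopifnot(inherits(params, "model_params"))
  if (length(rho) > 1L) return(vapply(rho, effective_mic, 0, params = params))
  if (!is.finite(rho) || rho < 0)
    stop("'rho' must be finite and non-negative", call. = FALSE)
  if (rho == 0) return(params$a_th)
  lo <- params$a_th * (1 + 1e-12)
  hi <- 2 * params$a_th
  while (critical_density(params, hi) <= rho) hi <- 2 * hi
  stats::uniroot(function(a) critical_density(params, a) - rho,
                 lower = lo, upper = hi, tol = 1e-12 * hi)$root
}

#' Critical occupancy of a sub-volume
#'
#' The smallest integer cell count whose density in a sub-volume `v` exceeds
#' the critical density: `N* = max(1, ceiling(rho* v))`. A sub-volume whose
#' initial count reaches `N*` survives; note `N* = 1` in the extreme
#' fragmentation regime where even a single cell exceeds the critical density
#' (`1/v > rho*`).
#'
#' @inheritParams critical_density
#' @param a_init initial antibiotic concentration, ug/ml, `>= a_th`.
#' @param sub_volume sub-volume size, ml.
#' @return Positive integer count.
#' @export
#' @examples
#' critical_count(model_params(), a_init = 35, sub_volume = 1e-6)  # 75
critical_count <- function(params, a_init, sub_volume) {
  if (any(sub_volume <= 0)) stop("'sub_volume' must be positive", call. = FALSE)
  pmax(1, ceiling(critical_density(params, a_init) * sub_volume))
}

#' Survival probability of one Poisson-occupied sub-volume
#'
#' With occupancy `X ~ Poisson(rho * v)`, a sub-volume survives when
#' `X >= N*`, so `ps = P(X >= N*)`, the upper Poisson tail. Computed with
#' [stats::ppois()] (regularised incomplete gamma), which is numerically
#' stable for mean occupancies up to 1e4 and beyond; naive term-by-term
#' summation is kept only as an oracle in the test suite.
#'
#' @inheritParams critical_count
#' @param rho mean population density, cells/ml.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' p <- model_params()
#' subpop_survival_prob(p, a_init = 15, rho = 5e7, sub_volume = 1e-7)
subpop_survival_prob <- function(params, a_init, rho, sub_volume) {
  if (any(rho < 0)) stop("'rho' must be non-negative", call. = FALSE)
  lambda <- rho * sub_volume
  nstar <- critical_count(params, a_init, sub_volume)
  stats::ppois(nstar - 1, lambda, lower.tail = FALSE)
}

#' Sub-volume survival probability conditional on initial occupancy
#'
#' `P(X >= N*) / P(X >= 1)`: the survival probability of a sub-volume known
#' to contain at least one cell. This is the relevant per-patch quantity in
#' the non-lethal regime, where fragmentation strands some occupied patches
#' below the critical density.
#'
#' @inheritParams subpop_survival_prob
#' @return Probability in `[0, 1]`; exactly 1 when `N* = 1`.
#' @export
conditional_subpop_survival_prob <- function(params, a_init, rho, sub_volume) {
  lambda <- rho * sub_volume
  if (any(lambda <= 0))
    stop("conditional survival requires positive mean occupancy", call. = FALSE)
  nstar <- critical_count(params, a_init, sub_volume)
  # tail ratio via log survival functions for stability at tiny lambda
  exp(stats::ppois(nstar - 1, lambda, lower.tail = FALSE, log.p = TRUE) -
        stats::ppois(0, lambda, lower.tail = FALSE, log.p = TRUE))
}

#' Whole-population survival probability under fragmentation
#'
#' The metapopulation survives if any of its `m` independent sub-volumes
#' survives: `Ps = 1 - (1 - ps)^m`, evaluated as `-expm1(m * log1p(-ps))`
#' so that tiny `ps` with large `m` does not lose precision.
#'
#' @param ps per-sub-volume survival probability in `[0, 1]`.
#' @param m number of sub-volumes (positive integer).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' total_survival_prob(0.5, 2)  # 0.75
total_survival_prob <- function(ps, m) {
  if (any(ps < 0 | ps > 1)) stop("'ps' must lie in [0, 1]", call. = FALSE)
  if (any(m < 1)) stop("'m' must be >= 1", call. = FALSE)
  ifelse(ps == 1, 1, -expm1(m * log1p(-ps)))
}

#' Survival probability in the extreme fragmentation limit
#'
#' When sub-volumes are so small that a single cell already exceeds the
#' critical density (`1/v > rho*`, hence `N* = 1`), a sub-volume survives
#' iff it is occupied, and the whole-population survival probability
#' collapses to `1 - exp(-rho V)` — independent of the degree of
#' fragmentation `m`, because `(1 - (1 - e^{-rho v}))^m = e^{-rho V}`.
#'
#' @param rho mean population density, cells/ml.
#' @param total_volume total habitat volume V, ml.
#' @return Probability in `[0, 1]`. The caller is responsible for checking
#'   that the regime condition `1/v > rho*` actually holds.
#' @export
extreme_fragmentation_survival <- function(rho, total_volume) {
  if (any(rho < 0) || any(total_volume <= 0))
    stop("'rho' must be >= 0 and 'total_volume' > 0", call. = FALSE)
  -expm1(-rho * total_volume)
}

#' Coefficient of variation of sub-volume density under Poisson filling
#'
#' For occupancy `X ~ Poisson(lambda)` with `lambda = rho v`, the CV of the
#' per-sub-volume count (equivalently of the local density) is
#' `1/sqrt(lambda)`. At fixed `rho` and `V` this grows as `sqrt(m)`: finer
#' fragmentation makes local densities more variable, which is the origin of
#' fragmentation rescue.
#'
#' @inheritParams extreme_fragmentation_survival
#' @param sub_volume sub-volume size, ml.
#' @return Dimensionless CV.
#' @export
occupancy_cv <- function(rho, sub_volume) {
  lambda <- rho * sub_volume
  if (any(lambda <= 0))
    stop("occupancy CV requires positive mean occupancy", call. = FALSE)
  1 / sqrt(lambda)
}

#' Tabulate the phase boundary over a grid of antibiotic concentrations
#'
#' @inheritParams critical_density
#' @param a_grid concentrations, ug/ml, all `>= a_th`.
#' @param file optional path; when given, the table is written as CSV with
#'   header `a_init_ug_per_ml,rho_star_cells_per_ml`.
#' @return A data frame with columns `a_init_ug_per_ml`,
#'   `rho_star_cells_per_ml` (invisibly when `file` is given).
#' @export
phase_boundary_table <- function(params, a_grid, file = NULL) {
  tab <- data.frame(a_init_ug_per_ml = a_grid,
                    rho_star_cells_per_ml = critical_density(params, a_grid))
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Wilson 95% score interval for a binomial proportion
#'
#' Used for all Monte-Carlo survival estimates. Wilson's interval remains
#' sensible at proportions near 0 and 1, which survival probabilities hit
#' constantly (e.g. `Ps` pinned at 0 or 1 across most of a fragmentation
#' sweep).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Construct a survival-probability estimate
#'
#' Light container pairing a probability with its provenance: Monte-Carlo
#' estimates carry a replicate count and Wilson 95% CI; analytic values carry
#' a degenerate interval.
#'
#' @param probability estimate in `[0, 1]`.
#' @param n_replicates replicate count (0 for analytic values).
#' @param method `"ANALYTIC"` or `"MONTE_CARLO"`.
#' @param n_survived successes, required for `"MONTE_CARLO"`.
#' @param n_undetermined replicates with no decided outcome (flagged, see
#'   [estimate_survival_probability()]).
#' @return An object of class `"survival_estimate"`.
#' @export
survival_estimate <- function(probability, n_replicates = 0L,
                              method = c("ANALYTIC", "MONTE_CARLO"),
                              n_survived = NULL, n_undetermined = 0L) {
  method <- match.arg(method)
  if (method == "MONTE_CARLO") {
    stopifnot(!is.null(n_survived), n_replicates >= 1)
    ci <- wilson_ci(n_survived, n_replicates)
  } else {
    ci <- c(probability, probability)
  }
  structure(list(probability = probability, n_replicates = n_replicates,
                 ci_low = ci[1], ci_high = ci[2], method = method,
                 n_undetermined = n_undetermined),
            class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat(sprintf("Survival probability: %.5g [%.5g, %.5g] (%s%s)\n",
              x$probability, x$ci_low, x$ci_high, x$method,
              if (x$method == "MONTE_CARLO")
                sprintf(", n = %d", x$n_replicates) else ""))
  if (x$n_undetermined > 0)
    cat(sprintf("  note: %d undetermined replicate(s)\n", x$n_undetermined))
  invisible(x)
}
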