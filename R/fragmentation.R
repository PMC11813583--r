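#' Fragmentation geometry of a habitat
#'
#' Describes the partitioning of a habitat of total volume `V` holding a
#' population of mean density `rho` into `m` equal sub-volumes `v = V/m`.
#' Cells are allocated stochastically, so a sub-volume's occupancy is
#' `Poisson(rho v)`; total population size and total volume are conserved in
#' expectation across degrees of fragmentation.
#'
#' @param total_volume total habitat volume; interpreted in `unit`.
#' @param m number of sub-volumes (positive integer).
#' @param mean_density mean population density rho, cells/ml.
#' @param seed RNG seed for occupancy sampling.
#' @param unit volume unit passed to [convert_volume()].
#' @return An object of class `"partition_spec"` with fields `total_volume`,
#'   `m`, `sub_volume`, `mean_density`, `seed`.
#' @export
#' @examples
#' partition_spec(total_volume = 1e8, m = 100, mean_density = 5e7,
#'                seed = 1, unit = "um3")  # 100 alveolus-sized pockets
partition_spec <- function(total_volume, m, mean_density, seed = 1L,
                           unit = "ml") {
  total_volume <- convert_volume(total_volume, unit)
  if (total_volume <= 0) stop("'total_volume' must be positive", call. = FALSE)
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (mean_density < 0) stop("'mean_density' must be >= 0", call. = FALSE)
  structure(list(total_volume = total_volume, m = as.integer(m),
                 sub_volume = total_volume / m, mean_density = mean_density,
                 seed = as.integer(seed)),
            class = "partition_spec")
}

#' Sample sub-volume occupancies
#'
#' Draws the initial cell count of each of the `m` sub-volumes as i.i.d.
#' `Poisson(rho v)`, the occupancy law observed for bacterial encapsulation
#' in microfluidic droplets.
#'
#' @param spec a [partition_spec()].
#' @return Integer vector of length `m`.
#' @export
sample_partition <- function(spec) {
  stopifnot(inherits(spec, "partition_spec"))
  set.seed(spec$seed)
  stats::rpois(spec$m, spec$mean_density * spec$sub_volume)
}

# Critical occupancy for a sub-volume, extended below threshold where any
# occupied sub-volume survives.
.nstar <- function(params, a_init, sub_volume) {
  if (a_init <= params$a_th) 1L else
    as.integer(critical_count(params, a_init, sub_volume))
}

#' Simulate a fragmented metapopulation
#'
#' Samples sub-volume occupancies, runs the per-sub-volume dynamics
#' independently in each (no exchange of cells or antibiotic between
#' sub-volumes), and aggregates into a whole-population outcome. With the
#' deterministic engine the per-sub-volume fate is the exact phase-boundary
#' criterion `n_i >= N*`, applied in vectorised form; regrowth times of
#' surviving sub-volumes come from the closed-form crossing time, so the
#' earliest-regrowing sub-volume is always one with maximal occupancy. With
#' the stochastic engine each occupied sub-volume runs [gillespie_run()] on
#' its own replicate seed.
#'
#' @param params a [model_params()] object.
#' @param spec a [partition_spec()].
#' @param a_init initial antibiotic concentration (uniform across
#'   sub-volumes), ug/ml.
#' @param engine `"deterministic"` or `"stochastic"`.
#' @param config [stochastic_config()] used by the stochastic engine.
#' @param keep_series also compute the summed population time series on a
#'   common grid (deterministic engine only; per-sub-volume trajectories are
#'   linearly interpolated onto the grid).
#' @param t_max,n_out grid controls used when `keep_series = TRUE`.
#' @return A list of class `"metapopulation_result"`: `n_init_counts`,
#'   `sub_outcomes`, `any_survived`, `earliest_regrowth_time` (`NA` if no
#'   sub-volume regrows), and (optionally) `times` / `total_pop_series`.
#' @export
simulate_metapopulation <- function(params, spec, a_init,
                                    engine = c("deterministic", "stochastic"),
                                    config = stochastic_config(),
                                    keep_series = FALSE,
                                    t_max = 2000, n_out = 200L) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "model_params"),
            inherits(spec, "partition_spec"))
  counts <- sample_partition(spec)
  v <- spec$sub_volume
  nstar <- .nstar(params, a_init, v)

  if (engine == "deterministic") {
    survived <- counts >= nstar
    outcomes <- ifelse(counts == 0L, "KILLED",
                       ifelse(survived, "SURVIVED", "KILLED"))
    regrow <- rep(NA_real_, spec$m)
    if (a_init <= params$a_th) {
      regrow[survived] <- 0
    } else if (any(survived)) {
      gap <- a_init - params$a_th + params$K_M * log(a_init / params$a_th)
      capacity <- params$enzyme_rate * counts[survived] / (params$gamma * v)
      regrow[survived] <- ifelse(capacity > gap,
                                 -log1p(-gap / capacity) / params$gamma,
                                 NA_real_)
    }
  } else {
    outcomes <- character(spec$m)
    regrow <- rep(NA_real_, spec$m)
    for (i in seq_len(spec$m)) {
      if (counts[i] == 0L) { outcomes[i] <- "KILLED"; next }
      cfg <- config
      cfg$seed <- as.integer(replicate_seed(spec$seed, i))
      run <- gillespie_run(params, initial_condition(counts[i], a_init, v),
                           cfg)
      outcomes[i] <- run$outcome
      regrow[i] <- run$t_threshold_crossing
    }
    survived <- outcomes == "SURVIVED"
  }

  res <- list(n_init_counts = counts, sub_outcomes = outcomes,
              any_survived = any(outcomes == "SURVIVED"),
              earliest_regrowth_time = if (any(!is.na(regrow)))
                min(regrow, na.rm = TRUE) else NA_real_,
              m = spec$m)
  if (keep_series) {
    times <- seq(0, t_max, length.out = n_out)
    total <- numeric(n_out)
    for (i in which(counts > 0L)) {
      tr <- simulate_deterministic(params,
                                   initial_condition(counts[i], a_init, v),
                                   t_max = t_max, n_out = n_out)
      total <- total + stats::approx(tr$times, tr$pop, xout = times,
                                     rule = 2)$y
    }
    res$times <- times
    res$total_pop_series <- total
  }
  class(res) <- "metapopulation_result"
  res
}

#' @export
print.metapopulation_result <- function(x, ...) {
  cat(sprintf("Metapopulation of %d sub-volumes: %d survived, %d killed%s\n",
              x$m, sum(x$sub_outcomes == "SURVIVED"),
              sum(x$sub_outcomes == "KILLED"),
              if (any(x$sub_outcomes == "UNDETERMINED"))
                sprintf(", %d undetermined",
                        sum(x$sub_outcomes == "UNDETERMINED")) else ""))
  cat(sprintf("  any_survived = %s\n", x$any_survived))
  invisible(x)
}

# Internal fast replicate: does any of m Poisson(lambda) sub-volumes reach
# nstar? Identical in law to simulate_metapopulation with the deterministic
# engine, without materialising per-sub-volume objects.
.any_survives <- function(m, lambda, nstar) {
  any(stats::rpois(m, lambda) >= nstar)
}

#' Whole-population survival across a fragmentation sweep
#'
#' For each antibiotic concentration and degree of fragmentation, estimates
#' the probability `Ps` that any sub-volume survives, by replicating the
#' entire m-sub-volume system (validating the independence assumption
#' end-to-end) and placing the analytic prediction
#' `Ps = 1 - (1 - ps)^m` alongside. Analytic values use the exact integer
#' critical count `N* = ceiling(rho* v)` — the source of the characteristic
#' zig-zag of the theory curve — never a smooth interpolation.
#'
#' @param params a [model_params()] object.
#' @param rho mean density, cells/ml (held fixed across the sweep).
#' @param a_init_list antibiotic concentrations to sweep, ug/ml.
#' @param total_volume habitat volume V, ml (held fixed; fragmentation
#'   varies `m` with `lambda = rho V / m`).
#' @param m_grid degrees of fragmentation; if `NULL`, derived from
#'   `lambda_grid`.
#' @param lambda_grid mean-occupancy grid used when `m_grid` is `NULL`
#'   (default: logarithmic from 200 down to 0.5).
#' @param n_replicates metapopulation replicates per grid point.
#' @param seed master seed.
#' @return Data frame `a_init, m, lambda, Ps_mc, ci_lo, ci_hi, Ps_analytic`.
#' @export
survival_curve <- function(params, rho, a_init_list, total_volume,
                           m_grid = NULL,
                           lambda_grid = 10^seq(log10(200), log10(0.5),
                                                length.out = 9),
                           n_replicates = 200L, seed = 1L) {
  if (is.null(m_grid))
    m_grid <- unique(pmax(1L, as.integer(round(rho * total_volume /
                                                 lambda_grid))))
  rows <- list()
  cell <- 0L
  for (a in a_init_list) {
    for (m in m_grid) {
      cell <- cell + 1L
      v <- total_volume / m
      lambda <- rho * v
      nstar <- .nstar(params, a, v)
      set.seed(replicate_seed(seed, cell))
      k <- sum(vapply(seq_len(n_replicates),
                      function(r) .any_survives(m, lambda, nstar), logical(1)))
      ci <- wilson_ci(k, n_replicates)
      ps <- if (a <= params$a_th) -expm1(-lambda)
            else subpop_survival_prob(params, a, rho, v)
      rows[[cell]] <- data.frame(a_init = a, m = m, lambda = lambda,
                                 Ps_mc = k / n_replicates,
                                 ci_lo = ci[1], ci_hi = ci[2],
                                 Ps_analytic = total_survival_prob(ps, m))
    }
  }
  do.call(rbind, rows)
}

#' Conditional sub-volume survival across a fragmentation sweep
#'
#' The non-lethal-regime counterpart of [survival_curve()]: for conditions
#' where the bulk population survives (`rho > rho*`), fragmentation strands
#' some occupied sub-volumes below the critical density. Reports the
#' Monte-Carlo survival frequency among initially occupied sub-volumes
#' (pooled over replicates) against the analytic conditional Poisson tail.
#'
#' @inheritParams survival_curve
#' @param m_grid degrees of fragmentation.
#' @return Data frame
#'   `a_init, m, lambda, ps_cond_mc, ci_lo, ci_hi, n_occupied,
#'    ps_cond_analytic`.
#' @export
conditional_survival_curve <- function(params, rho, a_init_list,
                                       total_volume,
                                       m_grid = c(1, 10, 100, 1000),
                                       n_replicates = 200L, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (a in a_init_list) {
    for (m in m_grid) {
      cell <- cell + 1L
      v <- total_volume / m
      lambda <- rho * v
      nstar <- .nstar(params, a, v)
      set.seed(replicate_seed(seed, cell))
      counts <- stats::rpois(m * n_replicates, lambda)
      occupied <- counts >= 1L
      n_occ <- sum(occupied)
      k <- sum(counts >= nstar)
      if (n_occ == 0) {
        est <- NA_real_; ci <- c(NA_real_, NA_real_)
      } else {
        est <- k / n_occ
        ci <- wilson_ci(k, n_occ)
      }
      ana <- if (a <= params$a_th) 1 else
        conditional_subpop_survival_prob(params, a, rho, v)
      rows[[cell]] <- data.frame(a_init = a, m = m, lambda = lambda,
                                 ps_cond_mc = est, ci_lo = ci[1],
                                 ci_hi = ci[2], n_occupied = n_occ,
                                 ps_cond_analytic = ana)
    }
  }
  do.call(rbind, rows)
}

#' Survival outcomes over an (antibiotic, density) grid
#'
#' Single-sub-volume phase scan: for every combination of initial antibiotic
#' concentration and mean density, draws Poisson occupancies for one
#' sub-volume of size `v` and records either a single stochastic outcome
#' (`n_replicates = 1`) or the mean survival frequency, alongside the
#' analytic Poisson-tail probability and the phase-boundary density
#' `rho*(a_init)`. Sub-volumes below the phase boundary retain a non-zero
#' survival probability whenever their mean occupancy is positive.
#'
#' @inheritParams survival_curve
#' @param a_grid antibiotic concentrations, ug/ml.
#' @param rho_grid mean densities, cells/ml.
#' @param sub_volume sub-volume size v, ml.
#' @param n_replicates occupancy draws per grid cell.
#' @return Data frame
#'   `a_init, rho, lambda, ps_mean, ps_analytic, rho_star, n_reps`.
#' @export
phase_scan <- function(params, a_grid, rho_grid, sub_volume,
                       n_replicates = 1L, seed = 1L) {
  rows <- list()
  cell <- 0L
  for (a in a_grid) {
    rho_star <- if (a <= params$a_th) 0 else critical_density(params, a)
    for (rho in rho_grid) {
      cell <- cell + 1L
      lambda <- rho * sub_volume
      nstar <- .nstar(params, a, sub_volume)
      set.seed(replicate_seed(seed, cell))
      k <- sum(stats::rpois(n_replicates, lambda) >= nstar)
      ana <- if (a <= params$a_th) -expm1(-lambda)
             else subpop_survival_prob(params, a, rho, sub_volume)
      rows[[cell]] <- data.frame(a_init = a, rho = rho, lambda = lambda,
                                 ps_mean = k / n_replicates,
                                 ps_analytic = ana, rho_star = rho_star,
                                 n_reps = n_replicates)
    }
  }
  do.call(rbind, rows)
}
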