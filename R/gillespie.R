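#' Configuration for the stochastic engine
#'
#' @param seed RNG seed for a single run.
#' @param t_max horizon, minutes; a run that reaches it with no decided
#'   outcome is labelled `UNDETERMINED`.
#' @param n_cap population ceiling at which survival is declared under the
#'   `"N_CAP"` rule.
#' @param survival_rule `"THRESHOLD_CROSSED"` (default): survival is declared
#'   the instant the antibiotic falls to the threshold with at least one cell
#'   alive — after that only births can occur, so extinction is impossible.
#'   `"N_CAP"`: survival is declared when the population reaches `n_cap`.
#' @return An object of class `"stochastic_config"`.
#' @export
stochastic_config <- function(seed = 1L, t_max = 5000,
                              n_cap = 1e6,
                              survival_rule = c("THRESHOLD_CROSSED", "N_CAP")) {
  survival_rule <- match.arg(survival_rule)
  if (!is.numeric(t_max) || t_max <= 0)
    stop("'t_max' must be positive", call. = FALSE)
  if (!is.numeric(n_cap) || n_cap < 1)
    stop("'n_cap' must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), t_max = t_max,
                 n_cap = n_cap, survival_rule = survival_rule),
            class = "stochastic_config")
}

#' One stochastic birth-death run with continuous antibiotic degradation
#'
#' Hybrid event-driven simulation of the defence model with demographic
#' noise: the cell count is an integer jump process (death at rate
#' `gamma * N` while `a > a_th`, birth at rate `mu * N` once `a <= a_th`)
#' while the antibiotic concentration decays continuously between events
#' following Michaelis-Menten kinetics at the current cell count. Because
#' the propensity is constant between events and the antibiotic admits an
#' implicit closed form at fixed `N`, the scheme is exact: waiting times are
#' exponential, the antibiotic update uses [advance_antibiotic()], and the
#' regime switch is located by the closed-form crossing time
#' ([antibiotic_crossing_time()]) whenever it precedes the next event — no
#' time-discretisation error is introduced anywhere.
#'
#' @param params a [model_params()] object.
#' @param init an [initial_condition()] object (integer `n_init`).
#' @param config a [stochastic_config()].
#' @param keep_trajectory record the full event log (times, event type,
#'   `N`, `a`); off by default since survival estimation needs only the
#'   outcome.
#' @return A `"trajectory"` with integer `pop`. Under the default rule,
#'   outcome `KILLED` means `N` hit 0 while `a > a_th`; `SURVIVED` means the
#'   antibiotic reached the threshold with `N >= 1`. `events` (when kept) is
#'   a data frame `t_min,event,N,a_ug_per_ml` with events `birth`, `death`,
#'   `switch`.
#' @export
#' @examples
#' p <- model_params()
#' run <- gillespie_run(p, initial_condition(5, 15, 100, "pl"),
#'                      stochastic_config(seed = 42))
#' run$outcome
gillespie_run <- function(params, init, config = stochastic_config(),
                          keep_trajectory = FALSE) {
  stopifnot(inherits(params, "model_params"),
            inherits(init, "initial_condition"),
            inherits(config, "stochastic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  V <- init$volume
  n <- init$n_init
  a <- init$a_init
  t <- 0
  t_cross <- NA_real_
  outcome <- NA_character_

  # event log in doubling buffers so long runs stay linear-time
  cap <- 1024L; used <- 0L
  log_t <- log_n <- log_a <- numeric(cap)
  log_e <- character(cap)
  rec <- function(ev) {
    if (!keep_trajectory) return(invisible())
    if (used == cap) {
      cap <<- cap * 2L
      length(log_t) <<- cap; length(log_n) <<- cap
      length(log_a) <<- cap; length(log_e) <<- cap
    }
    used <<- used + 1L
    log_t[used] <<- t; log_n[used] <<- n; log_a[used] <<- a
    log_e[used] <<- ev
  }
  rec("init")

  if (n == 0) {
    outcome <- "KILLED"
  }
  while (is.na(outcome)) {
    if (a > params$a_th) {
      # kill regime: race between the next death and the threshold crossing
      tc <- antibiotic_crossing_time(params, n, a, V)
      tau <- stats::rexp(1, rate = params$gamma * n)
      if (tc < tau) {
        if (t + tc > config$t_max) { outcome <- "UNDETERMINED"; break }
        t <- t + tc
        a <- params$a_th
        t_cross <- t
        rec("switch")
        if (config$survival_rule == "THRESHOLD_CROSSED") outcome <- "SURVIVED"
      } else {
        if (t + tau > config$t_max) { outcome <- "UNDETERMINED"; break }
        t <- t + tau
        a <- advance_antibiotic(params, n, a, tau, V)
        n <- n - 1L
        rec("death")
        if (n == 0L) outcome <- "KILLED"
      }
    } else {
      if (config$survival_rule == "THRESHOLD_CROSSED") { outcome <- "SURVIVED"; break }
      tau <- stats::rexp(1, rate = params$mu * n)
      if (t + tau > config$t_max) { outcome <- "UNDETERMINED"; break }
      t <- t + tau
      a <- advance_antibiotic(params, n, a, tau, V)
      n <- n + 1L
      rec("birth")
      if (n >= config$n_cap) outcome <- "SURVIVED"
    }
    if (t > config$t_max && is.na(outcome)) outcome <- "UNDETERMINED"
  }

  events <- if (keep_trajectory)
    data.frame(t_min = log_t[seq_len(used)], event = log_e[seq_len(used)],
               N = log_n[seq_len(used)], a_ug_per_ml = log_a[seq_len(used)])
  else NULL
  tt <- if (keep_trajectory) events$t_min else c(0, t)
  nn <- if (keep_trajectory) events$N else c(init$n_init, n)
  aa <- if (keep_trajectory) events$a_ug_per_ml else c(init$a_init, a)
  new_trajectory(tt, nn, aa, outcome, t_cross, events = events)
}

#' Monte-Carlo survival probability over replicate runs
#'
#' Replicates a single-sub-volume experiment `n_runs` times and returns the
#' fraction of surviving runs with a Wilson 95% confidence interval. The
#' initial cell count is either fixed or drawn fresh each replicate from a
#' Poisson occupancy law; the engine is either the stochastic birth-death
#' process or the deterministic classifier, so the effects of demographic
#' noise and partition noise can be switched on and off independently.
#'
#' Replicate `r` runs on the seed `replicate_seed(seed, r)` (a documented
#' counter scheme), so a master seed fully determines every replicate
#' regardless of execution order.
#'
#' @param params a [model_params()] object.
#' @param a_init initial antibiotic concentration, ug/ml.
#' @param volume sub-volume, ml.
#' @param occupancy either a single non-negative integer (fixed initial
#'   count) or `"poisson"` to draw `N_init ~ Poisson(lambda)` each replicate.
#' @param lambda mean occupancy, required when `occupancy = "poisson"`.
#' @param engine `"stochastic"` ([gillespie_run()]) or `"deterministic"`
#'   ([classify_outcome()]).
#' @param config a [stochastic_config()]; its seed field is ignored in
#'   favour of the per-replicate scheme.
#' @param n_runs number of replicates.
#' @param seed master seed.
#' @param exclude_undetermined drop `UNDETERMINED` replicates from the
#'   denominator instead of counting them as non-survivors (default FALSE;
#'   either way their count is reported).
#' @return A [survival_estimate()] with `method = "MONTE_CARLO"`.
#' @export
estimate_survival_probability <- function(params, a_init, volume,
                                          occupancy, lambda = NULL,
                                          engine = c("stochastic",
                                                     "deterministic"),
                                          config = stochastic_config(),
                                          n_runs = 1000L, seed = 1L,
                                          exclude_undetermined = FALSE) {
  engine <- match.arg(engine)
  if (n_runs < 1) stop("'n_runs' must be >= 1", call. = FALSE)
  poisson_occ <- identical(occupancy, "poisson")
  if (poisson_occ && (is.null(lambda) || lambda < 0))
    stop("Poisson occupancy requires a non-negative 'lambda'", call. = FALSE)
  n_survived <- 0L
  n_undet <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(replicate_seed(seed, r))
    n0 <- if (poisson_occ) stats::rpois(1, lambda) else as.integer(occupancy)
    init <- initial_condition(n0, a_init, volume)
    out <- if (engine == "deterministic") {
      classify_outcome(params, init)
    } else {
      cfg <- config; cfg$seed <- NULL  # RNG state already set for replicate r
      gillespie_run(params, init, cfg)$outcome
    }
    if (out == "SURVIVED") n_survived <- n_survived + 1L
    if (out == "UNDETERMINED") n_undet <- n_undet + 1L
  }
  denom <- if (exclude_undetermined) n_runs - n_undet else n_runs
  if (denom < 1) stop("all replicates were undetermined", call. = FALSE)
  survival_estimate(n_survived / denom, n_replicates = denom,
                    method = "MONTE_CARLO", n_survived = n_survived,
                    n_undetermined = n_undet)
}
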