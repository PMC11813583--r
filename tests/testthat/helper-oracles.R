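# Independent oracles used across the suite. These deliberately take the
# brute-force route (stiff ODE integration, naive probability summation) so
# they share no code path with the package's closed-form implementation.

# Reference parameter set used throughout (beta-lactamase defence).
ref_params <- function(...) model_params(...)

# Numerically integrate the threshold-switched defence model with deSolve.
# Returns a data frame t, N, a. A fine hmax bounds the error made by the
# discontinuous right-hand side at the regime switch.
oracle_defence_ode <- function(params, n0, a0, volume, t_max,
                               n_steps = 4000) {
  rhs <- function(t, y, parms) {
    kill <- y["a"] > params$a_th
    # floor the decay so doomed runs do not underflow the integrator
    dN <- if (kill) {
      if (y["N"] < 1e-200) 0 else -params$gamma * y["N"]
    } else {
      if (y["N"] > 1e12) 0 else params$mu * y["N"]
    }
    da <- if (y["a"] < 1e-12) 0 else
      -params$enzyme_rate * y["N"] / volume *
        y["a"] / (y["a"] + params$K_M)
    list(c(dN, da))
  }
  times <- seq(0, t_max, length.out = n_steps)
  out <- deSolve::lsoda(c(N = n0, a = a0), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12,
                        hmax = t_max / n_steps, maxsteps = 1e5)
  as.data.frame(out)
}

# Oracle crossing time: integrate degradation at constant N and locate the
# threshold by interpolation.
oracle_crossing_time <- function(params, n_cells, a0, volume, t_max) {
  rhs <- function(t, y, parms)
    list(-params$enzyme_rate * n_cells / volume * y / (y + params$K_M))
  times <- seq(0, t_max, length.out = 20000)
  out <- deSolve::lsoda(c(a = a0), times, rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  a <- out[, "a"]
  i <- which(a <= params$a_th)[1]
  if (is.na(i)) return(Inf)
  stats::approx(a[c(i - 1, i)], out[c(i - 1, i), "time"],
                xout = params$a_th)$y
}

# Oracle survival classification: does the ODE antibiotic reach the
# threshold (to within tol) while N > 0? Deterministic killing never hits
# N = 0, so survival is equivalent to the antibiotic crossing.
oracle_survives <- function(params, n0, a0, volume, t_max = 2e4) {
  if (n0 <= 0) return(FALSE)
  if (a0 <= params$a_th) return(TRUE)
  tr <- oracle_defence_ode(params, n0, a0, volume, t_max)
  min(tr$a) <= params$a_th * (1 + 1e-9)
}

# Brute-force upper Poisson tail P(X >= nstar) by pmf summation in log
# space, continued until terms are negligible.
oracle_poisson_tail <- function(lambda, nstar) {
  if (lambda == 0) return(as.numeric(nstar <= 0))
  if (nstar <= 0) return(1)
  j <- nstar:(nstar + max(200, ceiling(10 * lambda + 10 * sqrt(lambda))))
  sum(exp(-lambda + j * log(lambda) - lgamma(j + 1)))
}

# Numerically integrate the foraging model (nutrient n, substrate s, cells N).
oracle_foraging_ode <- function(fparams, n0, volume, t_max,
                                n_steps = 8000) {
  rhs <- function(t, y, parms) {
    release <- fparams$enzyme_rate * y["N"] / volume *
      y["s"] / (y["s"] + fparams$K_M)
    dN <- if (y["n"] >= fparams$n_th) fparams$mu * y["N"] else 0
    list(c(N = dN, n = release, s = -release))
  }
  times <- seq(0, t_max, length.out = n_steps)
  out <- deSolve::lsoda(c(N = n0, n = 0, s = fparams$s_init), times, rhs,
                        NULL, rtol = 1e-10, atol = 1e-12,
                        hmax = t_max / n_steps)
  as.data.frame(out)
}

# 99% equal-tailed binomial envelope check for a Monte-Carlo count.
# Quantiles are evaluated on whichever of p, 1-p is small, because qbinom's
# quantile search can stall when p is very close to 1.
within_binom_envelope <- function(k, n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  lo <- ifelse(p <= 0.5, stats::qbinom(a, n, p),
               n - stats::qbinom(1 - a, n, 1 - p))
  hi <- ifelse(p <= 0.5, stats::qbinom(1 - a, n, p),
               n - stats::qbinom(a, n, 1 - p))
  k >= lo & k <= hi
}
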