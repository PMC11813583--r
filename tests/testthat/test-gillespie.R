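p <- ref_params()

test_that("outcomes are certain in the degenerate regimes", {
  for (s in 1:5) {
    run <- gillespie_run(p, initial_condition(3, 0.5, 1e-7),
                         stochastic_config(seed = s))
    expect_identical(run$outcome, "SURVIVED")
  }
  run <- gillespie_run(p, initial_condition(0, 15, 1e-7),
                       stochastic_config(seed = 1))
  expect_identical(run$outcome, "KILLED")
  expect_equal(max(run$times), 0)
})

test_that("event log keeps antibiotic monotone with a single switch", {
  for (s in c(2, 9, 31)) {
    run <- gillespie_run(p, initial_condition(8, 15, 1e-7),
                         stochastic_config(seed = s),
                         keep_trajectory = TRUE)
    ev <- run$events
    expect_true(all(diff(ev$a_ug_per_ml) <= 1e-12))
    expect_lte(sum(ev$event == "switch"), 1)
    expect_true(all(abs(diff(ev$N)) %in% c(0, 1)))
  }
})

test_that("pure-death extinction times follow the max-of-exponentials law", {
  # with no enzyme the antibiotic never drops below threshold and each cell
  # dies independently at rate gamma: extinction time is the maximum of
  # N_init Exp(gamma) lifetimes
  p0 <- model_params(enzyme_rate = 0)
  n0 <- 10L
  n_runs <- 500
  times <- vapply(seq_len(n_runs), function(r) {
    run <- gillespie_run(p0, initial_condition(n0, 15, 1e-7),
                         stochastic_config(seed = r, t_max = 1e5))
    expect_identical(run$outcome, "KILLED")
    max(run$times)
  }, 0)
  ks <- suppressWarnings(
    ks.test(times, function(t) (1 - exp(-p0$gamma * t))^n0))
  expect_gt(ks$p.value, 0.01)
})

test_that("survival estimates are reproducible and correctly calibrated", {
  # deterministic engine + Poisson occupancy reduces to the analytic tail
  est <- estimate_survival_probability(p, a_init = 15, volume = 1e-7,
                                       occupancy = "poisson", lambda = 5,
                                       engine = "deterministic",
                                       n_runs = 1000, seed = 4)
  ps <- subpop_survival_prob(p, 15, 5e7, 1e-7)  # 0.5595
  expect_true(est$ci_low <= ps && ps <= est$ci_high)
  est2 <- estimate_survival_probability(p, a_init = 15, volume = 1e-7,
                                        occupancy = "poisson", lambda = 5,
                                        engine = "deterministic",
                                        n_runs = 1000, seed = 4)
  expect_identical(est$probability, est2$probability)
  # fixed inoculum above the critical count is certain survival
  est3 <- estimate_survival_probability(p, a_init = 15, volume = 1e-7,
                                        occupancy = 9, engine = "deterministic",
                                        n_runs = 50, seed = 1)
  expect_equal(est3$probability, 1)
})

test_that("CI half-width shrinks like the square root of the replicate count", {
  widths <- sapply(c(100, 10000), function(n) {
    est <- estimate_survival_probability(p, a_init = 15, volume = 1e-7,
                                         occupancy = "poisson", lambda = 5,
                                         engine = "deterministic",
                                         n_runs = n, seed = 2)
    est$ci_high - est$ci_low
  })
  expect_gt(widths[1] / widths[2], 8)
  expect_lt(widths[1] / widths[2], 12)
})

test_that("demographic noise rescues populations just below the boundary", {
  # mean occupancy ~2 cells below the critical count: partition noise alone
  # gives the Poisson tail; birth-death noise adds survival on top, because
  # a subpopulation can outlive its deterministic death sentence long
  # enough to finish degrading the antibiotic
  lambda <- critical_density(p, 15) * 1e-7 - 2  # ~2.13
  n_runs <- 2000
  p_det <- ppois(critical_count(p, 15, 1e-7) - 1, lambda,
                 lower.tail = FALSE)  # exact deterministic-engine value
  det <- estimate_survival_probability(p, 15, 1e-7, "poisson", lambda,
                                       engine = "deterministic",
                                       n_runs = n_runs, seed = 5)
  expect_true(det$ci_low <= p_det && p_det <= det$ci_high)
  sto <- estimate_survival_probability(p, 15, 1e-7, "poisson", lambda,
                                       engine = "stochastic",
                                       config = stochastic_config(t_max = 1e5),
                                       n_runs = n_runs, seed = 5)
  k_sto <- round(sto$probability * n_runs)
  test <- binom.test(k_sto, n_runs, p_det, alternative = "greater")
  expect_lt(test$p.value, 0.01)
})
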