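p <- ref_params()

test_that("partition sampling has Poisson moments and conserves mass", {
  spec <- partition_spec(1e-4, 10000, 5e8, seed = 3)  # lambda = 5
  counts <- sample_partition(spec)
  lambda <- spec$mean_density * spec$sub_volume
  expect_equal(lambda, 5, tolerance = 1e-12)
  expect_true(abs(mean(counts) - 5) < 3 * sqrt(5 / 10000))
  expect_true(var(counts) / mean(counts) > 0.95 &&
                var(counts) / mean(counts) < 1.05)
  # empty habitat
  expect_true(all(sample_partition(partition_spec(1e-4, 100, 0)) == 0))
  # conservation in expectation, independent of m
  for (m in c(1, 10, 100)) {
    tot <- vapply(1:2000, function(r)
      sum(sample_partition(partition_spec(1e-7, m, 5e7, seed = r))), 0)
    expect_true(abs(mean(tot) - 5) < 3 * sqrt(5 / 2000),
                info = paste("m =", m))
  }
})

test_that("single-compartment occupancy passes a chi-squared GOF test", {
  draws <- vapply(1:4000, function(r)
    sample_partition(partition_spec(1e-7, 1, 5e7, seed = r))[1], 0L)
  brk <- 0:9
  obs <- tabulate(pmin(draws, 9) + 1, nbins = 10)
  expe <- c(dpois(0:8, 5), ppois(8, 5, lower.tail = FALSE)) * 4000
  chi <- sum((obs - expe)^2 / expe)
  expect_gt(pchisq(chi, df = 9, lower.tail = FALSE), 0.01)
})

test_that("deterministic metapopulation outcome is the max-occupancy rule", {
  spec <- partition_spec(1e-5, 100, 4e7, seed = 17)
  res <- simulate_metapopulation(p, spec, a_init = 15)
  counts <- sample_partition(spec)
  nstar <- critical_count(p, 15, spec$sub_volume)
  expect_identical(res$n_init_counts, counts)
  expect_identical(res$any_survived, any(counts >= nstar))
  expect_identical(res$sub_outcomes == "SURVIVED", counts >= nstar)
  # earliest regrowth belongs to a maximally occupied sub-volume
  if (res$any_survived) {
    t_first <- res$earliest_regrowth_time
    i_max <- which(counts == max(counts))
    gap <- 15 - p$a_th + p$K_M * log(15 / p$a_th)
    cap <- p$enzyme_rate * max(counts) / (p$gamma * spec$sub_volume)
    expect_equal(t_first, -log1p(-gap / cap) / p$gamma, tolerance = 1e-10)
  }
  # empty habitat never survives
  empty <- simulate_metapopulation(p, partition_spec(1e-5, 50, 0), 15)
  expect_false(empty$any_survived)
})

test_that("stochastic metapopulation runs are reproducible sub-volume-wise", {
  spec <- partition_spec(1e-6, 10, 5e6, seed = 7)  # lambda = 0.5
  r1 <- simulate_metapopulation(p, spec, 15, engine = "stochastic")
  r2 <- simulate_metapopulation(p, spec, 15, engine = "stochastic")
  expect_identical(r1$sub_outcomes, r2$sub_outcomes)
  expect_true(all(r1$sub_outcomes[r1$n_init_counts == 0] == "KILLED"))
})

test_that("summed population series starts at the sampled total", {
  spec <- partition_spec(1e-6, 20, 5e7, seed = 2)
  res <- simulate_metapopulation(p, spec, 15, keep_series = TRUE,
                                 t_max = 500, n_out = 50)
  expect_equal(res$total_pop_series[1], sum(res$n_init_counts))
  expect_length(res$total_pop_series, 50)
})

test_that("Monte-Carlo survival matches the closed-form theory end-to-end", {
  cur <- survival_curve(p, 5e7, c(35, 55, 75), 1e-4,
                        lambda_grid = 10^seq(log10(200), log10(0.5),
                                             length.out = 7),
                        n_replicates = 150, seed = 11)
  expect_gte(nrow(cur), 20)
  k <- round(cur$Ps_mc * 150)
  expect_true(all(within_binom_envelope(k, 150, cur$Ps_analytic)))
  # and the analytic curve transitions from killing to certain survival
  for (a in c(35, 55, 75)) {
    sub <- cur[cur$a_init == a, ]
    expect_lt(sub$Ps_analytic[which.max(sub$lambda)], 0.05)
    expect_gt(sub$Ps_analytic[which.min(sub$lambda)], 0.95)
  }
})

test_that("phase scan keeps survival alive below the boundary", {
  scan <- phase_scan(p, a_grid = c(15, 35, 55), rho_grid = c(1e7, 5e7, 2e8),
                     sub_volume = 1e-7, n_replicates = 200, seed = 13)
  expect_true(all(scan$ps_analytic[scan$lambda > 0] > 0))
  k <- round(scan$ps_mean * scan$n_reps)
  expect_true(all(within_binom_envelope(k, scan$n_reps, scan$ps_analytic)))
  # far above the boundary with lambda >= 20, survival is near-certain
  far <- scan$rho > 3 * scan$rho_star & scan$lambda >= 20
  if (any(far)) expect_true(all(scan$ps_mean[far] > 0.99))
})

test_that("non-lethal fragmentation strands occupied sub-volumes", {
  cur <- conditional_survival_curve(p, 5e7, c(10, 15), 1e-4,
                                    m_grid = c(1, 10, 100, 1000),
                                    n_replicates = 100, seed = 19)
  for (a in c(10, 15)) {
    sub <- cur[cur$a_init == a, ]
    sub <- sub[order(sub$m), ]
    expect_true(all(diff(sub$ps_cond_analytic) <= 1e-12))
    expect_lt(sub$ps_cond_mc[sub$m == 1000], sub$ps_cond_mc[sub$m == 1])
  }
})
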