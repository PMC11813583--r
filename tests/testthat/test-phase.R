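p <- ref_params()

test_that("critical density reproduces the reference phase-boundary values", {
  rs <- critical_density(p, c(15, 35, 55, 75))
  expect_equal(rs, c(4.133e7, 7.434e7, 1.0395e8, 1.3233e8),
               tolerance = 1e-3)
  expect_equal(critical_density(p, p$a_th), 0)
  expect_error(critical_density(p, 0.5), "undefined")
})

test_that("critical density agrees with ODE bisection on the inoculum", {
  # independent route: bisect the (continuous) inoculum size at which the
  # integrated dynamics first reach the threshold, in a 100 pl droplet
  v <- 1e-7
  lo <- 1; hi <- 20
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    # integration is near-degenerate at the boundary itself (the crossing
    # recedes to infinity); truncation warnings there are expected and are
    # absorbed by the bisection tolerance
    ok <- suppressWarnings(oracle_survives(p, mid, 15, v, t_max = 2e4))
    if (ok) hi <- mid else lo <- mid
  }
  expect_equal(hi / v, critical_density(p, 15), tolerance = 1e-3)
})

test_that("effective MIC inverts the phase boundary", {
  expect_equal(effective_mic(p, 5e7), 19.86, tolerance = 1e-3)
  expect_equal(effective_mic(p, 0), p$a_th)
  for (rho in 10^(6:9))
    expect_equal(critical_density(p, effective_mic(p, rho)), rho,
                 tolerance = 1e-9)
})

test_that("critical count applies the ceiling with a floor of one cell", {
  expect_identical(critical_count(p, 35, 1e-6), 75)
  expect_identical(critical_count(p, 15, 1e-7), 5)
  # extreme fragmentation: one cell suffices when rho* v <= 1
  expect_identical(critical_count(p, 75, 1e-9), 1)
  expect_identical(critical_count(p, p$a_th, 1e-6), 1)
})

test_that("sub-volume survival probability equals the Poisson tail", {
  # lambda = 5, N* = 5 at a_init = 15 in a 100 pl droplet
  expect_equal(subpop_survival_prob(p, 15, 5e7, 1e-7), 0.559507,
               tolerance = 1e-5)
  expect_equal(subpop_survival_prob(p, 15, 5e7, 1e-7),
               oracle_poisson_tail(5, 5), tolerance = 1e-10)
  expect_equal(subpop_survival_prob(p, 75, 5e6, 1e-9),  # N* = 1
               -expm1(-5e6 * 1e-9), tolerance = 1e-12)
  expect_equal(subpop_survival_prob(p, 15, 0, 1e-7), 0)
  # stability at large mean occupancy, against the summation oracle
  expect_equal(subpop_survival_prob(p, 35, 8e7, 1e-4),
               oracle_poisson_tail(8e7 * 1e-4,
                                   critical_count(p, 35, 1e-4)),
               tolerance = 1e-9)
})

test_that("conditional survival is the tail ratio given occupancy", {
  expect_equal(conditional_subpop_survival_prob(p, 15, 5e7, 1e-7),
               0.563302, tolerance = 1e-5)
  expect_equal(conditional_subpop_survival_prob(p, 75, 5e6, 1e-9), 1)
  expect_equal(conditional_subpop_survival_prob(p, 15, 5e9, 1e-7), 1,
               tolerance = 1e-12)
  expect_error(conditional_subpop_survival_prob(p, 15, 0, 1e-7),
               "occupancy")
})

test_that("whole-population survival combines sub-volumes correctly", {
  expect_equal(total_survival_prob(0.5, 2), 0.75)
  expect_equal(total_survival_prob(0.3, 1), 0.3)
  # small-ps precision: log1p/expm1 route
  expect_equal(total_survival_prob(1e-12, 1e6), -expm1(1e6 * log1p(-1e-12)))
  # infection scenario: 5000 cells in 100 alveolus-sized sub-habitats
  ps <- subpop_survival_prob(p, 35, 5e7, 1e-6)
  expect_equal(ps, 5.7775e-4, tolerance = 1e-4)
  expect_equal(total_survival_prob(ps, 100), 0.056154, tolerance = 1e-4)
})

test_that("extreme fragmentation survival is m-independent occupancy", {
  expect_equal(extreme_fragmentation_survival(log(2) / 1e-4, 1e-4), 0.5)
  expect_equal(extreme_fragmentation_survival(0, 1e-4), 0)
  expect_equal(extreme_fragmentation_survival(5e7, 1e-4), 1)  # 5000 cells
})

test_that("occupancy CV grows with fragmentation", {
  expect_equal(occupancy_cv(25 / 1e-7, 1e-7), 0.2)
  expect_equal(occupancy_cv(4e7, 1e-7), 0.5)
  cv <- sapply(c(1, 10, 100), function(m) occupancy_cv(5e7, 1e-4 / m))
  expect_true(all(diff(cv) > 0))
  expect_error(occupancy_cv(0, 1e-7), "occupancy")
})

test_that("phase boundary is increasing, linear at high and log at low dose", {
  a <- seq(p$a_th, 100, length.out = 400)
  rs <- critical_density(p, a)
  expect_true(all(diff(rs) > 0))
  # slopes from finite differences; threshold far below both probe points
  pl <- model_params(a_th = 1e-6)
  slope <- function(a0) {
    h <- a0 * 1e-4
    (critical_density(pl, a0 + h) - critical_density(pl, a0 - h)) / (2 * h)
  }
  g_over_E <- pl$gamma / pl$enzyme_rate
  # a >> K_M: d rho*/da -> gamma/E (linear regime)
  expect_equal(slope(1e4 * pl$K_M), g_over_E, tolerance = 1e-3)
  # a << K_M: d rho*/da -> gamma K_M / (E a) (logarithmic regime)
  a_lo <- pl$K_M / 1e4
  expect_equal(slope(a_lo), g_over_E * pl$K_M / a_lo, tolerance = 1e-3)
})

test_that("analytic Ps is non-decreasing in fragmentation on the sweep grid", {
  V <- 1e-4; rho <- 5e7
  m_grid <- sort(unique(round(rho * V / 10^seq(log10(200), log10(0.5),
                                               length.out = 25))))
  for (a in c(35, 55, 75)) {
    Ps <- sapply(m_grid, function(m)
      total_survival_prob(subpop_survival_prob(p, a, rho, V / m), m))
    expect_true(all(diff(Ps) >= -1e-12), info = paste("a_init =", a))
  }
})

test_that("log Ps is approximately linear in sub-volume size mid-transition", {
  V <- 1e-4; rho <- 5e7
  m_grid <- unique(round(exp(seq(log(25), log(10000), length.out = 120))))
  for (a in c(35, 55)) {
    v <- V / m_grid
    Ps <- total_survival_prob(subpop_survival_prob(p, a, rho, v), m_grid)
    mid <- Ps > 0.01 & Ps < 0.9
    expect_gt(sum(mid), 5)
    expect_lt(cor(log(Ps[mid]), v[mid]), -0.95)
  }
})

test_that("Wilson interval is sane at the boundaries", {
  ci <- wilson_ci(0, 100)
  expect_equal(ci[1], 0)
  expect_gt(ci[2], 0)
  ci <- wilson_ci(200, 200)
  expect_equal(ci[2], 1)
  expect_lt(ci[1], 1)
  est <- survival_estimate(0.55, 200, "MONTE_CARLO", n_survived = 110)
  expect_true(est$ci_low <= est$probability && est$probability <= est$ci_high)
})

test_that("phase boundary table round-trips through CSV", {
  f <- tempfile(fileext = ".csv")
  tab <- phase_boundary_table(p, c(1, 15, 35), file = f)
  back <- read.csv(f)
  expect_identical(names(back),
                   c("a_init_ug_per_ml", "rho_star_cells_per_ml"))
  expect_equal(back$rho_star_cells_per_ml, tab$rho_star_cells_per_ml)
})
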