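test_that("vector field vanishes at the monomorphic corners and x-edges", {
  sys <- ecogame(panelb_incentives(), decaying_resource(1, 0.1))
  for (pt in list(c(0, 0), c(1, 1))) {
    f <- vector_field(sys, pt[1], pt[2])
    expect_equal(c(f$dx, f$dn), c(0, 0))
  }
  set.seed(21)
  n <- runif(20)
  expect_equal(vector_field(sys, rep(0, 20), n)$dx, rep(0, 20))
  expect_equal(vector_field(sys, rep(1, 20), n)$dx, rep(0, 20))
  expect_error(vector_field(sys, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("the strategy component is the replicator term x(1-x) g", {
  inc <- panelb_incentives()
  sys <- ecogame(inc, decaying_resource(1, 0.1))
  f <- vector_field(sys, 0.5, 0.5)
  expect_equal(f$dx, 0.25 * gain_corner_oracle(inc, 0.5, 0.5))
  expect_equal(f$dn, 0)
  set.seed(22)
  for (inc in rand_incentives(10)) {
    sys <- ecogame(inc, decaying_resource(2, 0.5))
    x <- runif(1); n <- runif(1)
    f <- vector_field(sys, x, n)
    expect_equal(f$dx, x * (1 - x) * gain_corner_oracle(inc, x, n),
                 tolerance = 1e-12)
  }
})

test_that("fixed starts stay fixed and x-edges are invariant", {
  sys <- ecogame(panelb_incentives(), decaying_resource(1, 0.3))
  tr <- integrate_ecogame(sys, 1, 1, 50)
  expect_true(all(tr$xs == 1) && all(tr$ns == 1))
  expect_equal(tr$metadata$termination, "converged")

  tr <- integrate_ecogame(sys, 1, 0.2, 80)
  expect_true(all(tr$xs == 1))
  expect_true(all(diff(tr$ns) >= -1e-12))      # n -> x monotonically
  expect_lt(abs(tr$ns[length(tr$ns)] - 1), 1e-4)

  # n-edges additionally invariant under tipping dynamics
  tipsys <- ecogame(panelb_incentives(),
                    tipping_environment(dist = "uniform", mu = 0.5, a = 0.5))
  tr <- integrate_ecogame(tipsys, 0.3, 0, 50)
  expect_true(all(tr$ns == 0))
})

test_that("trajectories stay inside the unit square", {
  set.seed(23)
  for (i in 1:40) {
    inc <- rand_incentives(1)[[1]]
    env <- if (i %% 2) decaying_resource(runif(1, 0.5, 2), runif(1, 0.05, 2))
           else renewing_resource(1, 1, 1, 0.1, 0.6, runif(1, 0.05, 2))
    tr <- integrate_ecogame(ecogame(inc, env), runif(1), runif(1), 150)
    expect_true(all(tr$xs >= 0 & tr$xs <= 1 & tr$ns >= 0 & tr$ns <= 1))
  }
})

test_that("compiled and reference integrators agree", {
  sys <- ecogame(panelb_incentives(), decaying_resource(1, 0.2))
  te <- seq(0, 60, length.out = 500)
  a <- integrate_ecogame(sys, 0.9, 0.3, 60, t_eval = te)
  b <- integrate_ecogame(sys, 0.9, 0.3, 60, t_eval = te, method = "R")
  expect_lt(max(abs(a$xs - b$xs), abs(a$ns - b$ns)), 1e-7)

  un <- tipping_environment(dist = "uniform", mu = 0.5, a = 0.5, epsilon = 1)
  sys <- ecogame(panelc_incentives(), un)
  a <- integrate_ecogame(sys, 0.4, 0.7, 60, t_eval = te)
  b <- integrate_ecogame(sys, 0.4, 0.7, 60, t_eval = te, method = "R")
  expect_lt(max(abs(a$xs - b$xs), abs(a$ns - b$ns)), 1e-7)
})

test_that("custom tipping CDFs integrate through the reference path", {
  # a custom quantile identical to the uniform closed form must reproduce it
  un <- tipping_environment(dist = "uniform", mu = 0.45, a = 0.7, epsilon = 1)
  cu <- tipping_environment(dist = "custom", epsilon = 1,
                            quantile_fn = function(p) 0.45 - 0.35 + 0.7 * p)
  te <- seq(0, 40, length.out = 400)
  a <- integrate_ecogame(ecogame(panelb_incentives(), un), 0.6, 0.4, 40,
                         t_eval = te)
  b <- integrate_ecogame(ecogame(panelb_incentives(), cu), 0.6, 0.4, 40,
                         t_eval = te)
  expect_lt(max(abs(a$xs - b$xs), abs(a$ns - b$ns)), 1e-6)
})

test_that("orbits are invariant to a joint timescale rescaling", {
  # multiplying both the gain and epsilon by c reparameterizes time by 1/c
  inc <- panelb_incentives()
  c0 <- 3
  inc_scaled <- incentive_params(c0 * inc$deltaL1, c0 * inc$deltaH1,
                                 c0 * inc$dL0, c0 * inc$dH0)
  te <- seq(0, 90, length.out = 600)
  tr1 <- integrate_ecogame(ecogame(inc, decaying_resource(1, 0.1)),
                           0.8, 0.3, 90, t_eval = te)
  tr2 <- integrate_ecogame(ecogame(inc_scaled, decaying_resource(1, c0 * 0.1)),
                           0.8, 0.3, 90 / c0, t_eval = te / c0)
  expect_lt(max(abs(tr1$xs - tr2$xs), abs(tr1$ns - tr2$ns)), 1e-6)
})

test_that("zero-gain systems drift onto n = x without moving x", {
  sys <- ecogame(incentive_params(0, 0, 0, 0), decaying_resource(1, 0.5))
  grid <- simulate_grid(sys, 3, t_end = 150)
  expect_equal(grid$x_end, grid$x0, tolerance = 1e-9)
  expect_equal(grid$n_end, grid$x0, tolerance = 1e-6)
  expect_equal(nrow(grid), 9)
})

test_that("simulate() draws reproducible starts and honors explicit ones", {
  sys <- ecogame(panelb_incentives(), decaying_resource(1, 0.2))
  a <- simulate(sys, nsim = 2, seed = 7, t_end = 10)
  b <- simulate(sys, nsim = 2, seed = 7, t_end = 10)
  expect_equal(a[[1]]$xs, b[[1]]$xs)
  expect_equal(a[[2]]$metadata$x0, b[[2]]$metadata$x0)
  tr <- simulate(sys, x0 = 0.5, n0 = 0.5, t_end = 5)
  expect_s3_class(tr, "ecogame_trajectory")
  expect_equal(tr$metadata$x0, 0.5)
})

test_that("system objects print and expose coefficients", {
  sys <- ecogame(panelb_incentives(), decaying_resource(1, 0.2))
  expect_equal(coef(sys), c(deltaL1 = 2, deltaH1 = 1, dL0 = 3, dH0 = 1))
  expect_output(print(sys), "Decaying resource")
  expect_output(print(integrate_ecogame(sys, 0.5, 0.5, 1)), "trajectory")
})
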