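test_that("interior equilibria match the dense sign-scan oracle", {
  # one coexistence equilibrium for the panel-b example incentives
  ieq <- interior_equilibria(panelb_incentives())
  expect_length(ieq, 1)
  expect_equal(ieq[[1]]$x_star, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(ieq[[1]]$n_star, ieq[[1]]$x_star)
  scan <- sign_scan_roots(panelb_incentives())
  expect_equal(ieq[[1]]$x_star, scan, tolerance = 1e-9)

  # two for the mixed-incentive example
  ieq4 <- interior_equilibria(panelc_incentives())
  expect_length(ieq4, 2)
  expect_equal(vapply(ieq4, function(e) e$x_star, numeric(1)),
               sign_scan_roots(panelc_incentives()), tolerance = 1e-9)
  expect_equal(vapply(ieq4, function(e) e$kind, character(1)),
               c("interior_minus", "interior_plus"))

  # g(x, x) = -(1-x)^2 - x^2 < 0 throughout: no interior equilibrium
  none <- interior_equilibria(incentive_params(1, 0, 0, -1))
  expect_length(none, 0)

  expect_error(interior_equilibria(incentive_params(0, 0, 0, 0)),
               class = "ecogames_continuum_error")
})

test_that("systems have 2 edge equilibria plus up to 2 interior ones", {
  dec <- decaying_resource(1, 1)
  eqs3 <- all_equilibria(ecogame(panelb_incentives(), dec))
  expect_length(eqs3, 3)
  eqs4 <- all_equilibria(ecogame(panelc_incentives(), dec))
  expect_length(eqs4, 4)
  kinds <- vapply(eqs4, function(e) e$kind, character(1))
  expect_equal(sum(kinds %in% c("edge_poor", "edge_rich")), 2)
  set.seed(31)
  for (inc in rand_incentives(40)) {
    eqs <- tryCatch(all_equilibria(ecogame(inc, dec)),
                    ecogames_continuum_error = function(e) NULL)
    if (is.null(eqs)) next
    expect_true(length(eqs) %in% 2:4)
  }
})

test_that("the closed-form Jacobian matches finite differences", {
  skip_if_not_installed("numDeriv")
  set.seed(32)
  envs <- list(decaying_resource(1.3, 0.4),
               renewing_resource(1, 2, 0.8, 0.2, 1, 0.6),
               tipping_environment(dist = "uniform", mu = 0.45, a = 0.7,
                                   epsilon = 0.8),
               weitz_limit_environment(theta = 2, eps_tilde = 0.5))
  for (env in envs) {
    for (rep in 1:5) {
      inc <- rand_incentives(1)[[1]]
      sys <- ecogame(inc, env)
      x <- runif(1, 0.05, 0.95); n <- runif(1, 0.05, 0.95)
      J <- jacobian_at(sys, x, n)
      Jnum <- numDeriv::jacobian(function(y) {
        f <- vector_field(sys, y[1], y[2]); c(f$dx, f$dn)
      }, c(x, n))
      expect_equal(unname(J), Jnum, tolerance = 1e-6)
    }
  }
})

test_that("the poor-edge Jacobian has the documented closed form", {
  inc <- panelc_incentives()
  eps <- 0.3; alpha <- 1.7
  sys <- ecogame(inc, decaying_resource(alpha, eps))
  J <- jacobian_at(sys, 0, 0)
  expect_equal(unname(J),
               matrix(c(inc$dH0, eps * alpha, 0, -eps * alpha), 2, 2))
})

test_that("stability labels follow the edge conditions and saddle property", {
  dec <- decaying_resource(1, 0.5)
  # leading the environmental movement unrewarded: poor edge stable
  s1 <- ecogame(incentive_params(1, 2, 1, -1), dec)
  eq <- classify_equilibrium(s1, c(0, 0))
  expect_match(eq$label, "^stable")
  # gold rush profitable: rich edge not stable (repelling along the
  # strategy direction, attracting along the environmental one: a saddle)
  s2 <- ecogame(panelb_incentives(), dec)
  expect_false(grepl("^stable", classify_equilibrium(s2, c(1, 1))$label))
  # x+* is always a saddle
  s3 <- ecogame(panelc_incentives(), dec)
  plus <- Filter(function(e) e$kind == "interior_plus", all_equilibria(s3))
  expect_equal(plus[[1]]$label, "saddle")
  expect_error(classify_equilibrium(s2, c(0.5, 0.5)), "not a fixed point")
})

test_that("edge stability is equivalent to the incentive sign conditions", {
  set.seed(33)
  dec <- decaying_resource(1, 0.8)
  for (inc in rand_incentives(60)) {
    if (abs(inc$dH0) < 1e-3 || abs(inc$deltaL1) < 1e-3) next
    sys <- ecogame(inc, dec)
    poor <- classify_equilibrium(sys, c(0, 0))
    rich <- classify_equilibrium(sys, c(1, 1))
    expect_equal(grepl("^stable", poor$label), inc$dH0 < 0)
    expect_equal(grepl("^stable", rich$label), inc$deltaL1 < 0)
  }
})

test_that("analytic equilibria agree with a Newton sweep (spot draws)", {
  set.seed(34)
  dec <- decaying_resource(1, 1)
  checked <- 0
  for (inc in rand_incentives(80)) {
    eqs <- tryCatch(all_equilibria(ecogame(inc, dec)),
                    ecogames_continuum_error = function(e) NULL)
    if (is.null(eqs) || !is_generic_draw(eqs)) next
    ana <- t(vapply(eqs, function(e) c(e$x_star, e$n_star), numeric(2)))
    ana <- ana[order(ana[, 1]), , drop = FALSE]
    nw <- newton_sweep_oracle(inc, res = 30)
    expect_equal(nrow(nw), nrow(ana))
    expect_lt(max(abs(nw - ana)), 1e-6)
    checked <- checked + 1
  }
  expect_gt(checked, 60)
})

test_that("the Hopf threshold is recovered identically by both methods", {
  dec <- decaying_resource(1, 1)
  ec_eig <- epsilon_crit(panelb_incentives(), dec)
  ec_tr <- epsilon_crit(panelb_incentives(), dec, method = "trace")
  expect_equal(ec_eig, ec_tr, tolerance = 1e-6)
  # closed form: x*(1-x*) gx / alpha at x* = 1/sqrt(3), gx = 2 - 3 x*
  xs <- 1 / sqrt(3)
  expect_equal(ec_tr, xs * (1 - xs) * (2 - 3 * xs), tolerance = 1e-12)

  set.seed(35)
  agreed <- 0
  while (agreed < 10) {
    v <- runif(4, 0.2, 5)
    inc <- incentive_params(v[1], v[2], v[3], v[4])
    if (!(inc$deltaH1 * inc$dL0 > inc$deltaL1 * inc$dH0 + 0.1)) next
    e1 <- epsilon_crit(inc, dec)
    e2 <- epsilon_crit(inc, dec, method = "trace")
    if (is.na(e1) || is.na(e2)) next
    expect_equal(e1, e2, tolerance = 1e-6)
    agreed <- agreed + 1
  }
})

test_that("no Hopf threshold exists outside the cycle conditions", {
  dec <- decaying_resource(1, 1)
  # follower incentives exactly balance leader incentives (common-pool case)
  expect_true(is.na(epsilon_crit(incentive_params(2, 2, 3, 3), dec)))
  # follower-sum condition violated
  expect_true(is.na(epsilon_crit(incentive_params(1, -3, 1, 1), dec)))
  # product condition violated
  expect_true(is.na(epsilon_crit(incentive_params(4, 1, 0.5, 3), dec)))
})

test_that("instability of x-* brackets the Hopf threshold", {
  set.seed(36)
  dec <- decaying_resource(1, 1)
  done <- 0
  while (done < 8) {
    v <- runif(4, 0.2, 4)
    inc <- incentive_params(v[1], v[2], v[3], v[4])
    ec <- epsilon_crit(inc, dec)
    if (is.na(ec)) next
    ieq <- interior_equilibria(inc)
    minus <- Filter(function(e) e$kind == "interior_minus", ieq)[[1]]
    lab_lo <- classify_equilibrium(
      ecogame(inc, decaying_resource(1, 0.9 * ec)),
      minus)$label
    lab_hi <- classify_equilibrium(
      ecogame(inc, decaying_resource(1, 1.1 * ec)),
      minus)$label
    expect_match(lab_lo, "^unstable")
    expect_match(lab_hi, "^stable")
    done <- done + 1
  }
})

test_that("regimes follow the incentive panels", {
  dec <- function(eps) decaying_resource(1, eps)
  # no incentive to lead either movement: bistable edges
  r <- classify_regime(incentive_params(-1, 0.5, -0.5, -1), dec(0.5))
  expect_equal(r$panel, "a")
  expect_equal(r$regime, "bistable_edges")

  # panel-b example: cycles below the threshold, coexistence above
  expect_equal(classify_regime(panelb_incentives(), dec(0.02))$regime,
               "limit_cycle")
  expect_equal(classify_regime(panelb_incentives(), dec(0.2))$regime,
               "stable_coexistence")

  # mixed-incentive ladder: stable interior, bistable cycle, dominance
  expect_equal(classify_regime(panelc_incentives(), dec(0.4))$regime,
               "bistable_edge_interior")
  expect_equal(classify_regime(panelc_incentives(), dec(0.25))$regime,
               "bistable_edge_cycle")
  expect_equal(classify_regime(panelc_incentives(), dec(0.05))$regime,
               "dominance_L")

  # no interior pair at all: plain dominance by the stable edge
  r <- classify_regime(incentive_params(-1, 0.2, 0.1, 0.5), dec(0.5))
  expect_equal(r$panel, "c")
  expect_equal(r$regime, "dominance_L")

  # degenerate continuum reported, not raised
  r <- classify_regime(incentive_params(0, 0, 0, 0), dec(0.5))
  expect_equal(r$regime, "boundary_degenerate")
})

test_that("renewing and decaying environments give the same regime", {
  set.seed(37)
  checked <- 0
  for (inc in rand_incentives(25)) {
    if (abs(inc$dH0) < 0.05 || abs(inc$deltaL1) < 0.05) next
    # the Hopf threshold differs slightly between families; classify at a
    # speed well inside the regime rather than on a boundary
    ecs <- c(epsilon_crit(inc, decaying_resource(1, 1)),
             epsilon_crit(inc, renewing_resource(1, 1, 1, 0.1, 0.5, 1)))
    eps <- if (all(is.na(ecs))) 0.35 else 0.5 * min(ecs, na.rm = TRUE)
    rd <- classify_regime(inc, decaying_resource(1, eps), probe = FALSE)
    rr <- classify_regime(inc, renewing_resource(1, 1, 1, 0.1, 0.5, eps),
                          probe = FALSE)
    expect_equal(rd$panel, rr$panel)
    expect_equal(rd$regime, rr$regime)
    checked <- checked + 1
  }
  expect_gt(checked, 15)
})

test_that("equilibria tabulate with eigenvalue columns", {
  eqs <- all_equilibria(ecogame(panelc_incentives(), decaying_resource(1, 0.3)))
  tab <- equilibria_table(eqs)
  expect_equal(nrow(tab), 4)
  expect_named(tab, c("kind", "x", "n", "re_eig1", "im_eig1",
                      "re_eig2", "im_eig2", "label"))
  # the interior saddle plus the unstable poor edge (also saddle-type here)
  expect_equal(tab$label[tab$kind == "interior_plus"], "saddle")
  expect_equal(sum(grepl("^stable", tab$label)), 2)
})
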