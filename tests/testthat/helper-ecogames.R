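# shared fixtures and independent oracles for the test suite

`%||%` <- function(a, b) if (is.null(a)) b else a

# the two worked incentive sets: a panel-b game (cycles vs coexistence) and
# a mixed-sign panel-c game (bistability, cycles, and dominance)
panelb_incentives <- function() incentive_params(deltaL1 = 2, deltaH1 = 1,
                                               dL0 = 3, dH0 = 1)
panelc_incentives <- function() incentive_params(deltaL1 = -1/8, deltaH1 = 4,
                                               dL0 = 1, dH0 = 2)

rand_incentives <- function(n, lim = 5) {
  lapply(seq_len(n), function(i) {
    v <- runif(4, -lim, lim)
    incentive_params(v[1], v[2], v[3], v[4])
  })
}

# oracle: payoff-difference computed entrywise from the interpolated matrix,
# pi_L - pi_H with pi_i = x * Pi[i, L] + (1 - x) * Pi[i, H]
gain_matrix_oracle <- function(p, x, n) {
  M <- payoff_matrix(p, n)
  piL <- x * M["L", "L"] + (1 - x) * M["L", "H"]
  piH <- x * M["H", "L"] + (1 - x) * M["H", "H"]
  piL - piH
}

# oracle: bilinear interpolation of the four corner values of the gain
gain_corner_oracle <- function(inc, x, n) {
  g00 <- inc$dH0; g10 <- inc$dL0
  g01 <- -inc$deltaH1; g11 <- -inc$deltaL1
  (1 - x) * (1 - n) * g00 + x * (1 - n) * g10 +
    (1 - x) * n * g01 + x * n * g11
}

# oracle: dense sign-scan for roots of g(x, x) on (0, 1); the diagonal gain
# is evaluated through the corner-interpolation route, independently of the
# quadratic-coefficient algebra under test
sign_scan_roots <- function(inc, step = 1e-6) {
  x <- seq(step, 1 - step, by = step)
  gd <- gain_corner_oracle(inc, x, x)
  flips <- which(gd[-1] * gd[-length(gd)] < 0)
  vapply(flips, function(i) {
    uniroot(function(z) gain_corner_oracle(inc, z, z),
            c(x[i], x[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

# oracle: vectorized Newton sweep from a dense grid for all fixed points of
# the decaying-resource system (alpha = 1, epsilon = 1), hand-coded field
newton_sweep_oracle <- function(inc, res = 50) {
  dL1 <- inc$deltaL1; dH1 <- inc$deltaH1; dl0 <- inc$dL0; dh0 <- inc$dH0
  g  <- function(x, n) (1-n)*(x*dl0+(1-x)*dh0) - n*(x*dL1+(1-x)*dH1)
  gx <- function(x, n) (1-n)*(dl0-dh0) - n*(dL1-dH1)
  gn <- function(x, n) -(x*dl0+(1-x)*dh0) - (x*dL1+(1-x)*dH1)
  u <- seq(0.001, 0.999, length.out = res)
  X <- rep(u, res); N <- rep(u, each = res)
  for (it in 1:40) {
    F1 <- X*(1-X)*g(X, N); F2 <- X - N
    J11 <- (1-2*X)*g(X, N) + X*(1-X)*gx(X, N)
    J12 <- X*(1-X)*gn(X, N)
    det <- -J11 - J12          # det of [[J11, J12], [1, -1]]
    det[abs(det) < 1e-14] <- NA
    dx <- (-F1 - F2*J12) / det
    dn <- (F2*J11 - F1) / det
    X <- pmin(pmax(X - dx, -0.25), 1.25)
    N <- pmin(pmax(N - dn, -0.25), 1.25)
  }
  F1 <- X*(1-X)*g(X, N)
  ok <- is.finite(X) & is.finite(N) &
    sqrt(F1^2 + (X - N)^2) < 1e-9 & X > -1e-7 & X < 1 + 1e-7
  pts <- unique(round(cbind(X[ok], N[ok]), 6))
  pts[order(pts[, 1]), , drop = FALSE]
}

# genericity screen for sweep comparisons: equilibria well separated and
# away from the boundary, so root counting is unambiguous
is_generic_draw <- function(eqs) {
  xs <- sort(vapply(eqs, function(e) e$x_star, numeric(1)))
  if (length(xs) > 1 && min(diff(xs)) < 1e-3) return(FALSE)
  interior <- xs[xs > 1e-12 & xs < 1 - 1e-12]
  all(interior > 1e-3 & interior < 1 - 1e-3)
}

# diagnose from a fresh dense-sampled integration
integrate_and_diagnose <- function(sys, x0, n0, t_end, n_eval = 8000, ...) {
  tr <- tryCatch(
    integrate_ecogame(sys, x0, n0, t_end,
                      t_eval = seq(0, t_end, length.out = n_eval), ...),
    ecogames_solver_error = function(e) e$trajectory)
  diagnose_attractor(tr)
}
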