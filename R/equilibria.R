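#' Interior equilibria on the environmental nullcline
#'
#' For renewing and decaying environments the environmental nullcline is
#' `n = x`, so interior fixed points are roots in `(0, 1)` of the quadratic
#' \deqn{g(x,x) = \delta_H^0 (1-x)^2 + (\delta_L^0 - \Delta_H^1) x (1-x)
#'       - \Delta_L^1 x^2.}
#' There are up to two such roots. The root at which the Jacobian
#' determinant is negative is the saddle `x+*` (kind `"interior_plus"`,
#' never stable); the other, `x-*` (`"interior_minus"`), can be stable or
#' can lose stability in a Hopf bifurcation. Because the determinant sign at
#' an interior root equals `-sign(d g(x,x)/dx)` for both environment
#' families, the kind is determined by the incentives alone.
#'
#' @param inc An [incentive_params()] object.
#' @return A list of 0, 1 or 2 equilibrium objects (see
#'   [classify_equilibrium()] for the filled-in form), each with
#'   `n_star = x_star`.
#' @section Degenerate games: if the quadratic vanishes identically
#'   (`g = 0` on the whole nullcline) every point of the diagonal is an
#'   equilibrium; an error of class `"ecogames_continuum_error"` is raised
#'   rather than returning an empty list.
#' @export
interior_equilibria <- function(inc) {
  stopifnot(inherits(inc, "incentive_params"))
  co <- nullcline_quadratic(inc)  # c(A, B, C): A x^2 + B x + C
  A <- co[1]; B <- co[2]; C <- co[3]
  scale <- max(abs(unlist(inc)), 1)
  if (all(abs(co) < 1e-12 * scale))
    stop(errorCondition(
      "degenerate game: g vanishes on the whole nullcline (continuum of equilibria)",
      class = c("ecogames_continuum_error", "error", "condition")))
  roots <- if (abs(A) < 1e-14 * max(abs(B), abs(C), 1)) {
    if (abs(B) < 1e-14 * max(abs(C), 1)) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else {
      # numerically stable quadratic roots
      qq <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
      unique(c(qq / A, if (qq != 0) C / qq else -B / A - qq / A))
    }
  }
  roots <- sort(roots[roots > 1e-12 & roots < 1 - 1e-12])
  lapply(roots, function(x) {
    slope <- 2 * A * x + B       # d g(x,x)/dx
    kind <- if (slope > 0) "interior_plus" else "interior_minus"
    new_equilibrium(x, x, kind)
  })
}

# coefficients (A, B, C) of g(x, x) = A x^2 + B x + C
nullcline_quadratic <- function(inc) {
  c(A = inc$dH0 - (inc$dL0 - inc$deltaH1) - inc$deltaL1,
    B = -2 * inc$dH0 + inc$dL0 - inc$deltaH1,
    C = inc$dH0)
}

new_equilibrium <- function(x_star, n_star, kind, eigenvalues = NULL,
                            label = NULL) {
  structure(list(x_star = x_star, n_star = n_star, kind = kind,
                 eigenvalues = eigenvalues, label = label),
            class = "ecogame_equilibrium")
}

#' All fixed points of an eco-evolutionary system
#'
#' A linear two-strategy system with a renewing or decaying environment has
#' up to four fixed points: the two monomorphic edge states `(0, 0)` and
#' `(1, 1)`, plus up to two interior coexistence equilibria on the `n = x`
#' nullcline. Each is returned classified (eigenvalues and stability label
#' filled in).
#'
#' @param sys An [ecogame()] system with renewing or decaying environment.
#' @return A list of classified equilibrium objects, kinds among
#'   `"edge_poor"`, `"edge_rich"`, `"interior_plus"`, `"interior_minus"`.
#' @export
all_equilibria <- function(sys) {
  stopifnot(inherits(sys, "ecogame"))
  if (inherits(sys$environment, "tipping_environment"))
    stop("analytic enumeration covers renewing/decaying environments; ",
         "probe tipping environments by simulation", call. = FALSE)
  eqs <- c(list(new_equilibrium(0, 0, "edge_poor"),
                new_equilibrium(1, 1, "edge_rich")),
           interior_equilibria(sys$incentives))
  lapply(eqs, function(eq) classify_equilibrium(sys, eq))
}

#' Jacobian of the eco-evolutionary vector field
#'
#' Exact closed-form partial derivatives (the gain is bilinear and all
#' environmental drifts are polynomial in `(x, n)`).
#'
#' @param sys An [ecogame()] system.
#' @param x,n Evaluation point in the unit square.
#' @return A 2x2 numeric matrix, rows = (`dx/dt`, `dn/dt`), columns =
#'   (`d/dx`, `d/dn`).
#' @export
jacobian_at <- function(sys, x, n) {
  stopifnot(inherits(sys, "ecogame"))
  check_unit(x, "x"); check_unit(n, "n")
  inc <- sys$incentives
  g <- gain(x, n, inc)
  j11 <- (1 - 2 * x) * g + x * (1 - x) * gain_dx(x, n, inc)
  j12 <- x * (1 - x) * gain_dn(x, n, inc)
  j21 <- env_drift_dx(sys$environment, x, n)
  j22 <- env_drift_dn(sys$environment, x, n)
  matrix(c(j11, j21, j12, j22), 2, 2,
         dimnames = list(c("dx", "dn"), c("x", "n")))
}

#' Classify the stability of a fixed point
#'
#' Fills in the eigenvalues of the Jacobian and a stability label:
#' negative determinant gives a saddle; otherwise the sign of the largest
#' eigenvalue real part separates stable from unstable, with node/focus by
#' realness of the eigenvalues, and `"nonhyperbolic"` returned when the
#' leading real part is within `1e-9` of zero.
#'
#' @param sys An [ecogame()] system.
#' @param eq An equilibrium object, or a length-2 vector `c(x, n)` that is a
#'   fixed point (vector-field norm below `1e-10`).
#' @return The equilibrium object with `eigenvalues` and `label` filled.
#' @export
classify_equilibrium <- function(sys, eq) {
  stopifnot(inherits(sys, "ecogame"))
  if (is.numeric(eq) && length(eq) == 2)
    eq <- new_equilibrium(eq[1], eq[2], "unspecified")
  if (!inherits(eq, "ecogame_equilibrium"))
    stop("`eq` must be an equilibrium or c(x, n)", call. = FALSE)
  fn <- field_norm(sys, eq$x_star, eq$n_star)
  if (fn >= 1e-10)
    stop(sprintf("(%g, %g) is not a fixed point (field norm %.3g)",
                 eq$x_star, eq$n_star, fn), call. = FALSE)
  J <- jacobian_at(sys, eq$x_star, eq$n_star)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  max_re <- max(Re(ev))
  complex_pair <- any(abs(Im(ev)) > 1e-12)
  eq$eigenvalues <- as.complex(ev)
  eq$label <-
    if (abs(max_re) < 1e-9) "nonhyperbolic"
    else if (dt < 0) "saddle"
    else if (max_re < 0) if (complex_pair) "stable_focus" else "stable_node"
    else if (complex_pair) "unstable_focus" else "unstable_node"
  eq
}

#' @export
print.ecogame_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (%s): (x*, n*) = (%.6g, %.6g)%s\n",
              x$kind, x$x_star, x$n_star,
              if (is.null(x$label)) "" else sprintf(" [%s]", x$label)))
  if (!is.null(x$eigenvalues))
    cat(sprintf("  eigenvalues: %s\n",
                paste(format(x$eigenvalues, digits = 6), collapse = ", ")))
  invisible(x)
}

#' Critical environmental-feedback speed (Hopf threshold)
#'
#' The interior equilibrium `x-*` can only lose stability when the incentive
#' structure satisfies \eqn{\Delta_H^1 + \delta_L^0 > 0} and
#' \eqn{\Delta_H^1 \delta_L^0 > \Delta_L^1 \delta_H^0}; it then does so for
#' environmental feedback slower than a critical speed,
#' \eqn{\epsilon < \epsilon_{crit}}. The primary computation (`"eigen"`)
#' bisects the sign change in the largest eigenvalue real part of the
#' Jacobian at `x-*` over `epsilon` in `(1e-8, 1e4)`. The `"trace"` method is
#' an independently derived closed form from the trace-zero Hopf condition,
#' \deqn{\epsilon_{crit} = x^*(1-x^*)\, g_x(x^*, x^*) / D,}
#' with `D = alpha` for a decaying and `D = r - q(eL x* + eH(1-x*))` for a
#' renewing resource; it is valid when the determinant at that `epsilon` is
#' positive, and the two methods agree to high relative accuracy wherever
#' both apply.
#'
#' @param inc An [incentive_params()] object.
#' @param env_family A [renewing_resource()] or [decaying_resource()] (its
#'   own `epsilon` is irrelevant here).
#' @param method `"eigen"` (bisection, default) or `"trace"` (closed form).
#' @return The critical speed (positive number), or `NA` when `x-*` does not
#'   exist, the incentive conditions fail, or no sign change exists
#'   (no Hopf threshold).
#' @export
epsilon_crit <- function(inc, env_family, method = c("eigen", "trace")) {
  stopifnot(inherits(inc, "incentive_params"))
  if (!inherits(env_family, c("renewing_resource", "decaying_resource")))
    stop("epsilon_crit is defined for renewing/decaying environments",
         call. = FALSE)
  method <- match.arg(method)
  ieq <- tryCatch(interior_equilibria(inc),
                  ecogames_continuum_error = function(e) NULL)
  if (is.null(ieq)) return(NA_real_)
  minus <- Filter(function(e) e$kind == "interior_minus", ieq)
  if (length(minus) == 0) return(NA_real_)
  xs <- minus[[1]]$x_star
  if (!(inc$deltaH1 + inc$dL0 > 0)) return(NA_real_)
  if (!(inc$deltaH1 * inc$dL0 > inc$deltaL1 * inc$dH0)) return(NA_real_)
  if (method == "trace") {
    D <- if (inherits(env_family, "decaying_resource")) env_family$alpha
         else env_family$r - env_family$q *
           (env_family$eL * xs + env_family$eH * (1 - xs))
    ec <- xs * (1 - xs) * gain_dx(xs, xs, inc) / D
    if (!(ec > 0)) return(NA_real_)
    # Hopf requires a positive determinant at the crossing
    det_ok <- (gain_dx(xs, xs, inc) + gain_dn(xs, xs, inc)) < 0
    return(if (det_ok) ec else NA_real_)
  }
  max_re <- function(eps) {
    env <- env_with_epsilon(env_family, eps)
    J <- jacobian_at(ecogame(inc, env), xs, xs)
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  lo <- 1e-8; hi <- 1e4
  flo <- max_re(lo); fhi <- max_re(hi)
  if (is.na(flo) || is.na(fhi) || sign(flo) == sign(fhi)) return(NA_real_)
  for (i in 1:200) {
    mid <- 0.5 * (lo + hi)
    fm <- max_re(mid)
    if (fm == 0) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    if ((hi - lo) < 1e-13 * hi) break
  }
  0.5 * (lo + hi)
}

env_with_epsilon <- function(env, epsilon) {
  env$epsilon <- epsilon
  if (inherits(env, "tipping_environment") && identical(env$dist, "heaviside"))
    env$eps_tilde <- epsilon / (1 + env$theta)
  env
}

#' Classify the global dynamical regime
#'
#' Determines the qualitative long-run outcome of a linear eco-evolutionary
#' game from the incentive signs, the interior-equilibrium structure, the
#' cycle conditions, and the feedback speed relative to
#' [epsilon_crit()]:
#' * panel `"a"` (`deltaL1 < 0`, `dH0 < 0`): both edges stable, only the
#'   interior saddle exists -- `bistable_edges`.
#' * panel `"b"` (both positive): neither edge stable; `limit_cycle` when
#'   the follower conditions hold and `epsilon < epsilon_crit`, else
#'   `stable_coexistence`.
#' * panels `"c"`/`"d"` (mixed signs): one stable edge. Without interior
#'   equilibria the stable edge dominates (`dominance_L`/`dominance_H`).
#'   With an interior pair, a stable `x-*` gives `bistable_edge_interior`;
#'   an unstable `x-*` gives either `bistable_edge_cycle` or (when the
#'   feedback is too slow to sustain a cycle) edge dominance -- the
#'   sub-boundary is resolved by a deterministic simulation probe
#'   (`t_end = 500/epsilon` from five interior starts).
#'
#' When any defining inequality sits within `1e-9` of equality the regime is
#' reported as `boundary_degenerate` rather than forced into a generic
#' class.
#'
#' @param inc An [incentive_params()] object.
#' @param env An environment object carrying the `epsilon` to classify at
#'   (renewing or decaying).
#' @param probe Logical; allow the simulation fallback in panels c/d
#'   (default `TRUE`).
#' @return An object of class `"ecogame_regime"`: list with `panel`,
#'   `regime`, `epsilon`, `epsilon_crit`, `conditions` (evaluated
#'   inequalities) and `equilibria`.
#' @export
classify_regime <- function(inc, env, probe = TRUE) {
  stopifnot(inherits(inc, "incentive_params"))
  if (!inherits(env, c("renewing_resource", "decaying_resource")))
    stop("regime classification covers renewing/decaying environments",
         call. = FALSE)
  eps <- env$epsilon
  tol <- 1e-9
  lead_rich <- inc$deltaL1   # incentive to lead the gold rush
  lead_poor <- inc$dH0       # incentive to lead the environmental movement
  eq15 <- inc$deltaH1 + inc$dL0
  eq16 <- inc$deltaH1 * inc$dL0 - inc$deltaL1 * inc$dH0
  ec <- epsilon_crit(inc, env)
  conds <- list(deltaL1 = lead_rich, dH0 = lead_poor,
                followers_sum = eq15, follower_product_margin = eq16,
                epsilon = eps, epsilon_crit = ec)
  sys <- ecogame(inc, env)
  ieq <- tryCatch(interior_equilibria(inc),
                  ecogames_continuum_error = function(e) "continuum")
  mk <- function(regime, panel, equilibria = NULL, note = NULL) {
    structure(list(panel = panel, regime = regime, epsilon = eps,
                   epsilon_crit = ec, conditions = conds,
                   equilibria = equilibria, note = note),
              class = "ecogame_regime")
  }
  panel <- if (lead_rich < 0 && lead_poor < 0) "a"
           else if (lead_rich > 0 && lead_poor > 0) "b"
           else if (lead_rich < 0 && lead_poor > 0) "c"
           else "d"
  if (identical(ieq, "continuum"))
    return(mk("boundary_degenerate", panel, note = "continuum of equilibria"))
  if (abs(lead_rich) < tol || abs(lead_poor) < tol)
    return(mk("boundary_degenerate", panel, note = "edge incentive at zero"))
  eqs <- all_equilibria(sys)
  if (panel == "a") return(mk("bistable_edges", "a", eqs))
  minus <- Filter(function(e) e$kind == "interior_minus", eqs)
  if (panel == "b") {
    if (abs(eq16) < tol || (!is.na(ec) && abs(eps - ec) < tol))
      return(mk("boundary_degenerate", "b", eqs, "on a cycle-region boundary"))
    cyclic <- eq15 > 0 && eq16 > 0 && !is.na(ec) && eps < ec
    return(mk(if (cyclic) "limit_cycle" else "stable_coexistence", "b", eqs))
  }
  dominant <- if (panel == "c") "dominance_L" else "dominance_H"
  if (length(minus) == 0) {
    if (length(eqs) > 2)  # tangency: interior pair collapsed to one point
      return(mk("boundary_degenerate", panel, eqs, "interior tangency"))
    return(mk(dominant, panel, eqs))
  }
  if (!is.na(ec) && abs(eps - ec) < tol)
    return(mk("boundary_degenerate", panel, eqs, "epsilon at epsilon_crit"))
  stable_minus <- minus[[1]]$label %in% c("stable_node", "stable_focus")
  if (stable_minus) return(mk("bistable_edge_interior", panel, eqs))
  if (!probe) return(mk("bistable_edge_cycle", panel, eqs,
                        "unprobed: cycle assumed where x-* is unstable"))
  has_cycle <- probe_for_cycle(sys, minus[[1]])
  mk(if (has_cycle) "bistable_edge_cycle" else dominant, panel, eqs,
     "sub-regime resolved by simulation probe")
}

# deterministic simulation probe used to separate cycle-supporting from
# edge-dominated sub-regimes in the mixed-incentive panels
probe_for_cycle <- function(sys, minus_eq) {
  eps <- sys$environment$epsilon
  t_end <- 500 / eps
  xs <- minus_eq$x_star
  starts <- rbind(c(min(xs + 0.02, 0.98), min(xs + 0.02, 0.98)),
                  c(max(xs - 0.02, 0.02), min(xs + 0.02, 0.98)),
                  c(0.5, 0.5), c(0.25, 0.75), c(0.75, 0.25))
  for (i in seq_len(nrow(starts))) {
    tr <- tryCatch(
      integrate_ecogame(sys, starts[i, 1], starts[i, 2], t_end,
                        t_eval = seq(0, t_end, length.out = 6000)),
      ecogames_solver_error = function(e) e$trajectory)
    d <- diagnose_attractor(tr, extend = FALSE)
    if (d$kind == "limit_cycle") return(TRUE)
  }
  FALSE
}

#' @export
print.ecogame_regime <- function(x, ...) {
  cat(sprintf("Dynamical regime: %s (incentive panel %s)\n", x$regime, x$panel))
  cat(sprintf("  epsilon = %g; epsilon_crit = %s\n", x$epsilon,
              if (is.na(x$epsilon_crit)) "none" else format(x$epsilon_crit)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Summarize an eco-evolutionary system
#'
#' Enumerates and classifies all fixed points and reports the dynamical
#' regime and Hopf threshold (renewing/decaying environments).
#'
#' @param object An [ecogame()] system.
#' @param probe Passed to [classify_regime()].
#' @param ... Unused.
#' @return An object of class `"summary.ecogame"`.
#' @export
summary.ecogame <- function(object, probe = TRUE, ...) {
  reg <- classify_regime(object$incentives, object$environment, probe = probe)
  structure(list(sys = object, regime = reg,
                 equilibria = reg$equilibria %||% all_equilibria(object)),
            class = "summary.ecogame")
}

#' @export
print.summary.ecogame <- function(x, ...) {
  print(x$sys)
  cat("\nFixed points:\n")
  for (eq in x$equilibria) print(eq)
  cat("\n")
  print(x$regime)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate equilibria
#'
#' @param eqs A list of classified equilibria (from [all_equilibria()]).
#' @return A data frame with columns `kind, x, n, re_eig1, im_eig1, re_eig2,
#'   im_eig2, label`.
#' @export
equilibria_table <- function(eqs) {
  if (inherits(eqs, "ecogame_equilibrium")) eqs <- list(eqs)
  do.call(rbind, lapply(eqs, function(e) {
    ev <- e$eigenvalues %||% c(NA_complex_, NA_complex_)
    data.frame(kind = e$kind, x = e$x_star, n = e$n_star,
               re_eig1 = Re(ev[1]), im_eig1 = Im(ev[1]),
               re_eig2 = Re(ev[2]), im_eig2 = Im(ev[2]),
               label = e$label %||% NA_character_)
  }))
}
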