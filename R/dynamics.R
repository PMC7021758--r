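#' Couple a game to an environment
#'
#' Assembles the two-dimensional eco-evolutionary system
#' \deqn{dx/dt = x(1-x)\,g(x,n), \qquad dn/dt = \mathrm{drift}(x,n),}
#' where `x` is the frequency of the low-impact strategy, `n` the normalized
#' environmental state, `g` the bilinear payoff advantage of L (see
#' [gain()]), and the drift is set by the environment class. The strategy
#' update speed is normalized to one, so the environment's `epsilon` is the
#' single remaining timescale ratio. The mean fitness of the replicator
#' equation is never computed: the two-strategy reduction eliminates it
#' exactly.
#'
#' @param incentives An [incentive_params()] object (or a
#'   [payoff_structure()], which is reduced via
#'   [incentives_from_payoffs()] -- the replicator dynamics depend only on
#'   the payoff difference).
#' @param environment An environment object ([renewing_resource()],
#'   [decaying_resource()] or [tipping_environment()]).
#' @return An object of class `"ecogame"` with components `incentives` and
#'   `environment`.
#' @examples
#' sys <- ecogame(incentive_params(2, 1, 3, 1), decaying_resource(1, 0.1))
#' vector_field(sys, 0.5, 0.5)
#' @export
ecogame <- function(incentives, environment) {
  if (inherits(incentives, "payoff_structure"))
    incentives <- incentives_from_payoffs(incentives)
  if (!inherits(incentives, "incentive_params"))
    stop("`incentives` must be incentive_params or payoff_structure",
         call. = FALSE)
  if (!inherits(environment, "eco_environment"))
    stop("`environment` must be an eco_environment", call. = FALSE)
  structure(list(incentives = incentives, environment = environment),
            class = "ecogame")
}

#' Eco-evolutionary vector field
#'
#' @param sys An [ecogame()] system.
#' @param x,n Coordinates in the unit square (vectorized).
#' @return A list with components `dx` and `dn`.
#' @export
vector_field <- function(sys, x, n) {
  stopifnot(inherits(sys, "ecogame"))
  list(dx = x * (1 - x) * gain(x, n, sys$incentives),
       dn = env_drift(sys$environment, x, n))
}

field_norm <- function(sys, x, n) {
  f <- vector_field(sys, x, n)
  sqrt(f$dx^2 + f$dn^2)
}

# encode a system for the C++ integrator; NA when only the R path applies
sys_par_vector <- function(sys) {
  inc <- sys$incentives
  env <- sys$environment
  base <- c(inc$deltaL1, inc$deltaH1, inc$dL0, inc$dH0)
  if (inherits(env, "renewing_resource")) {
    c(base, 0, env$epsilon, env$r, env$k, env$q, env$eL, env$eH, 0, 0, 0, 0)
  } else if (inherits(env, "decaying_resource")) {
    c(base, 1, env$epsilon, 0, 0, 0, 0, 0, env$alpha, 0, 0, 0)
  } else if (identical(env$dist, "uniform")) {
    c(base, 2, env$epsilon, 0, 0, 0, 0, 0, 0, env$mu, env$a, 0)
  } else if (identical(env$dist, "heaviside")) {
    c(base, 3, env$eps_tilde, 0, 0, 0, 0, 0, 0, 0, 0, env$theta)
  } else {
    NULL
  }
}

#' Integrate an eco-evolutionary system
#'
#' Adaptive Dormand-Prince 5(4) integration of the coupled
#' strategy-environment dynamics from an initial condition in the unit
#' square. States are clipped to `[0, 1]` after each accepted step; an
#' excursion beyond `clip_tol` aborts with an error that carries the partial
#' trajectory. Integration terminates early with reason `"converged"` once
#' the vector-field norm stays below `1e-10` for a sustained window, so slow
#' passages near saddles are not misreported as converged.
#'
#' @param sys An [ecogame()] system.
#' @param x0,n0 Initial condition in `[0, 1]`.
#' @param t_end Final time, positive.
#' @param rtol,atol Solver tolerances (defaults `1e-9`; cycle amplitudes
#'   near a Hopf point are tolerance-sensitive).
#' @param t_eval Optional increasing vector of output times in
#'   `[0, t_end]`; states are obtained by cubic Hermite interpolation of the
#'   accepted steps. Without it the accepted steps themselves are returned.
#' @param clip_tol Containment violation threshold (default `1e-8`).
#' @param method `"auto"` uses compiled code for the closed-form environment
#'   classes and pure R otherwise; `"R"` forces the reference R integrator.
#' @return An object of class `"ecogame_trajectory"`: a list with `times`,
#'   `xs`, `ns`, the generating `sys`, and `metadata` (tolerances,
#'   termination reason, step count).
#' @examples
#' sys <- ecogame(incentive_params(2, 1, 3, 1), decaying_resource(1, 0.2))
#' tr <- integrate_ecogame(sys, x0 = 0.9, n0 = 0.4, t_end = 200)
#' tail(as.data.frame(tr), 1)  # settles at the interior equilibrium
#' @export
integrate_ecogame <- function(sys, x0, n0, t_end, rtol = 1e-9, atol = 1e-9,
                              t_eval = NULL, clip_tol = 1e-8,
                              method = c("auto", "R")) {
  stopifnot(inherits(sys, "ecogame"))
  check_unit(x0, "x0")
  check_unit(n0, "n0")
  if (!(t_end > 0)) stop("t_end must be positive", call. = FALSE)
  if (!(rtol > 0 && atol > 0)) stop("tolerances must be positive", call. = FALSE)
  method <- match.arg(method)
  par <- sys_par_vector(sys)
  res <- if (!is.null(par) && method == "auto") {
    .dp45_integrate(par, x0, n0, t_end, rtol, atol, t_eval,
                    clip_tol = clip_tol)
  } else {
    r_dp45(function(x, n) {
      f <- vector_field(sys, min(max(x, 0), 1), min(max(n, 0), 1))
      c(f$dx, f$dn)
    }, x0, n0, t_end, rtol, atol, t_eval, clip_tol = clip_tol)
  }
  reason <- switch(as.character(res$status),
                   "0" = "t_end", "1" = "converged",
                   "2" = "containment_violation", "3" = "max_steps",
                   "4" = "step_underflow")
  if (!is.null(t_eval) && res$status %in% c(0, 1)) {
    # fill evaluation times past an early (converged) exit with the final state
    filled <- res$n_eval_filled
    if (filled < length(t_eval)) {
      idx <- seq.int(filled + 1, length(t_eval))
      res$x_eval[idx] <- res$x[length(res$x)]
      res$n_eval[idx] <- res$n[length(res$n)]
    }
    times <- as.numeric(t_eval); xs <- res$x_eval; ns <- res$n_eval
  } else {
    times <- res$t; xs <- res$x; ns <- res$n
  }
  xs <- pmin(pmax(xs, 0), 1)
  ns <- pmin(pmax(ns, 0), 1)
  traj <- structure(
    list(times = times, xs = xs, ns = ns, sys = sys,
         metadata = list(rtol = rtol, atol = atol, t_end = t_end,
                         termination = reason, nsteps = res$nsteps,
                         x0 = x0, n0 = n0)),
    class = "ecogame_trajectory")
  if (res$status %in% c(2, 4)) {
    cond <- errorCondition(
      sprintf("integration aborted (%s) at t = %g", reason,
              res$t[length(res$t)]),
      trajectory = traj, class = "ecogames_solver_error")
    stop(cond)
  }
  traj
}

# Reference pure-R Dormand-Prince 5(4); same contracts as the compiled path.
# Used for custom tipping CDFs and as an independent-path cross-check.
r_dp45 <- function(f, x0, n0, t_end, rtol, atol, t_eval = NULL,
                   clip_tol = 1e-8, conv_tol = 1e-10, conv_window = 5,
                   max_steps = 2e6) {
  A <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656))
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  y <- c(x0, n0)
  t <- 0
  k1 <- f(y[1], y[2])
  Ts <- t; Xs <- y[1]; Ns <- y[2]
  n_eval <- length(t_eval); i_eval <- 0
  Ex <- En <- rep(NA_real_, n_eval)
  while (i_eval < n_eval && t_eval[i_eval + 1] <= 0) {
    i_eval <- i_eval + 1; Ex[i_eval] <- y[1]; En[i_eval] <- y[2]
  }
  h <- min(1e-3, t_end / 10)
  status <- 0L; quiet_since <- -1; steps <- 0
  K <- matrix(0, 7, 2)
  while (t < t_end) {
    if (steps > max_steps) { status <- 3L; break }
    if (h < 1e-14 * max(1, abs(t))) { status <- 4L; break }
    h <- min(h, t_end - t)
    K[1, ] <- k1
    for (i in 1:5) {
      yi <- y + h * drop(A[[i]] %*% K[seq_len(i), , drop = FALSE])
      K[i + 1, ] <- f(yi[1], yi[2])
    }
    y5 <- y + h * drop(b5[1:6] %*% K[1:6, ])
    K[7, ] <- f(y5[1], y5[2])
    y4 <- y + h * drop(b4 %*% K)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    steps <- steps + 1
    if (err <= 1 || h <= 1e-13) {
      if (i_eval < n_eval) {
        while (i_eval < n_eval && t_eval[i_eval + 1] <= t + h) {
          th <- (t_eval[i_eval + 1] - t) / h
          h00 <- (1 + 2 * th) * (1 - th)^2; h10 <- th * (1 - th)^2
          h01 <- th^2 * (3 - 2 * th);       h11 <- th^2 * (th - 1)
          i_eval <- i_eval + 1
          Ex[i_eval] <- h00 * y[1] + h10 * h * K[1, 1] +
            h01 * y5[1] + h11 * h * K[7, 1]
          En[i_eval] <- h00 * y[2] + h10 * h * K[1, 2] +
            h01 * y5[2] + h11 * h * K[7, 2]
        }
      }
      t <- t + h; y <- y5; k1 <- K[7, ]
      viol <- max(-y, y - 1)
      if (viol > clip_tol) {
        status <- 2L; Ts <- c(Ts, t); Xs <- c(Xs, y[1]); Ns <- c(Ns, y[2])
        break
      }
      y <- pmin(pmax(y, 0), 1)
      Ts <- c(Ts, t); Xs <- c(Xs, y[1]); Ns <- c(Ns, y[2])
      k1 <- f(y[1], y[2])
      fn <- sqrt(sum(k1^2))
      if (fn < conv_tol) {
        if (quiet_since < 0) quiet_since <- t
        else if (t - quiet_since >= conv_window) { status <- 1L; break }
      } else quiet_since <- -1
    }
    fac <- if (err > 0) 0.9 * err^(-0.2) else 5
    h <- h * min(5, max(0.2, fac))
  }
  out <- list(t = Ts, x = Xs, n = Ns, status = status, nsteps = steps)
  if (n_eval > 0) {
    out$t_eval <- t_eval; out$x_eval <- Ex; out$n_eval <- En
    out$n_eval_filled <- i_eval
  }
  out
}

#' @export
print.ecogame <- function(x, ...) {
  cat("Eco-evolutionary game system\n")
  print(x$incentives)
  print(x$environment)
  invisible(x)
}

#' @export
coef.ecogame <- function(object, ...) {
  unlist(object$incentives)
}

#' @export
print.ecogame_trajectory <- function(x, ...) {
  np <- length(x$times)
  cat(sprintf(
    "Eco-evolutionary trajectory: %d points over t in [0, %g] (%s)\n",
    np, x$times[np], x$metadata$termination))
  cat(sprintf("  start (x, n) = (%g, %g); end (%.6g, %.6g)\n",
              x$metadata$x0, x$metadata$n0, x$xs[np], x$ns[np]))
  invisible(x)
}

#' @export
as.data.frame.ecogame_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$xs, n = x$ns)
}

#' Simulate trajectories from an eco-evolutionary system
#'
#' With explicit `x0`, `n0` this is a thin wrapper around
#' [integrate_ecogame()]; otherwise `nsim` initial conditions are drawn
#' uniformly from the open unit square (reproducibly under `seed`).
#'
#' @param object An [ecogame()] system.
#' @param nsim Number of trajectories when initial conditions are drawn.
#' @param seed Optional RNG seed for the drawn initial conditions.
#' @param x0,n0 Optional explicit initial condition.
#' @param t_end Final time.
#' @param ... Passed on to [integrate_ecogame()].
#' @return A single `"ecogame_trajectory"` (explicit start or `nsim = 1`),
#'   else a list of trajectories.
#' @importFrom stats simulate runif coef
#' @export
simulate.ecogame <- function(object, nsim = 1, seed = NULL,
                             x0 = NULL, n0 = NULL, t_end = 200, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(x0) || !is.null(n0)) {
    if (is.null(x0) || is.null(n0))
      stop("supply both x0 and n0, or neither", call. = FALSE)
    return(integrate_ecogame(object, x0, n0, t_end, ...))
  }
  starts <- matrix(runif(2 * nsim, 0.05, 0.95), ncol = 2)
  out <- lapply(seq_len(nsim), function(i)
    integrate_ecogame(object, starts[i, 1], starts[i, 2], t_end, ...))
  if (nsim == 1) out[[1]] else out
}

#' Integrate from every interior point of a regular grid
#'
#' Runs one integration per interior grid point of the unit square and
#' collects terminal diagnostics. Per-point solver failures are recorded,
#' not propagated, so a failing cell does not abort the grid.
#'
#' @param sys An [ecogame()] system.
#' @param grid_resolution Number of interior points per axis (`>= 2`).
#' @param t_end Integration time per point.
#' @param ... Passed to [integrate_ecogame()].
#' @return A data frame with one row per grid point: starting point, terminal
#'   state, termination reason, and terminal vector-field norm. The
#'   trajectories themselves are attached as attribute `"trajectories"`.
#' @export
simulate_grid <- function(sys, grid_resolution, t_end = 200, ...) {
  stopifnot(inherits(sys, "ecogame"))
  if (!(grid_resolution >= 2)) stop("grid_resolution must be >= 2", call. = FALSE)
  u <- seq_len(grid_resolution) / (grid_resolution + 1)
  starts <- expand.grid(x0 = u, n0 = u)
  trajs <- vector("list", nrow(starts))
  rows <- lapply(seq_len(nrow(starts)), function(i) {
    tr <- tryCatch(
      integrate_ecogame(sys, starts$x0[i], starts$n0[i], t_end, ...),
      ecogames_solver_error = function(e) e$trajectory)
    trajs[[i]] <<- tr
    np <- length(tr$times)
    data.frame(x0 = starts$x0[i], n0 = starts$n0[i],
               x_end = tr$xs[np], n_end = tr$ns[np],
               termination = tr$metadata$termination,
               field_norm = field_norm(sys, tr$xs[np], tr$ns[np]))
  })
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  out
}
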