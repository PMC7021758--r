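#' Self-renewing resource environment
#'
#' A resource stock `m` that grows logistically (rate `r`, carrying capacity
#' `k`) and is harvested at per-capita efforts `eL` (low-impact strategy) and
#' `eH` (high-impact strategy) with catchability `q`:
#' \deqn{dm/dt = r m (1 - m/k) - q m (e_L x + e_H (1-x)).}
#' After the affine normalization of [stock_to_state()], the environmental
#' state obeys
#' \deqn{dn/dt = \epsilon\,(r - q(e_L n + e_H(1-n)))\,(x - n),}
#' so the environment relaxes toward the attracting nullcline `n = x`.
#'
#' Efforts must satisfy `0 <= eL < eH < r/q` so that the stock is positive at
#' both monomorphic equilibria.
#'
#' @param r Intrinsic growth rate (1/time), positive.
#' @param k Carrying capacity (stock units), positive.
#' @param q Catchability (1/(effort time)), positive.
#' @param eL,eH Harvest efforts of the low- and high-impact strategies.
#' @param epsilon Speed of environmental dynamics relative to strategy
#'   updating (dimensionless), positive.
#' @return An environment object of class
#'   `c("renewing_resource", "eco_environment")`.
#' @seealso [decaying_resource()], [tipping_environment()], [env_drift()]
#' @export
renewing_resource <- function(r, k, q, eL, eH, epsilon = 1) {
  stopifnot(is.numeric(r), is.numeric(k), is.numeric(q),
            is.numeric(eL), is.numeric(eH), is.numeric(epsilon))
  if (!(r > 0 && k > 0 && q > 0))
    stop("r, k, q must be positive", call. = FALSE)
  if (!(eL >= 0 && eL < eH && eH < r / q))
    stop("efforts must satisfy 0 <= eL < eH < r/q", call. = FALSE)
  if (!(epsilon > 0)) stop("epsilon must be positive", call. = FALSE)
  structure(list(r = r, k = k, q = q, eL = eL, eH = eH, epsilon = epsilon),
            class = c("renewing_resource", "eco_environment"))
}

#' Decaying resource (pollutant) environment
#'
#' A pollutant stock `m` with first-order decay at rate `alpha`, emitted at
#' rates `eL` and `eH` by the two strategies:
#' \deqn{dm/dt = -\alpha m + e_L x + e_H (1-x).}
#' In normalized coordinates (with `n = 1` the clean state reached under pure
#' low-impact play) the state obeys \eqn{dn/dt = \epsilon\,\alpha\,(x - n)}.
#'
#' @param alpha Decay rate (1/time), positive.
#' @param eL,eH Optional emission rates (`0 <= eL < eH`); only needed for the
#'   raw-stock transforms [stock_to_state()] / [state_to_stock()].
#' @param epsilon Relative speed of environmental dynamics, positive.
#' @return An environment object of class
#'   `c("decaying_resource", "eco_environment")`.
#' @export
decaying_resource <- function(alpha, epsilon = 1, eL = NULL, eH = NULL) {
  if (!is.numeric(alpha) || !(alpha > 0))
    stop("alpha must be positive", call. = FALSE)
  if (!(epsilon > 0)) stop("epsilon must be positive", call. = FALSE)
  if (!is.null(eL) || !is.null(eH)) {
    if (is.null(eL) || is.null(eH) || !(eL >= 0 && eL < eH))
      stop("emission rates must satisfy 0 <= eL < eH", call. = FALSE)
  }
  structure(list(alpha = alpha, eL = eL, eH = eH, epsilon = epsilon),
            class = c("decaying_resource", "eco_environment"))
}

#' Tipping-point environment
#'
#' The environment consists of a continuum of units that flip state when the
#' strategy frequency crosses their individual tipping threshold. With `F`
#' the cumulative distribution of thresholds, the environmental state obeys
#' \deqn{dn/dt = \epsilon\, n (1-n)\, (x - F^{-1}(n)),}
#' which leaves `n = 0` and `n = 1` exactly invariant.
#'
#' Three variants are provided:
#' * `dist = "uniform"`: thresholds uniform on `[mu - a/2, mu + a/2]`, giving
#'   the closed form \eqn{dn/dt = \epsilon n(1-n)(x - a n + a/2 - \mu)}.
#' * `dist = "heaviside"`: all thresholds equal (the zero-variance limit of
#'   the uniform case); the drift uses the equivalent limiting form
#'   \eqn{\tilde\epsilon\, n(1-n)(\theta x - (1-x))} with tipping point
#'   `mu = 1/(1+theta)` and `epsilon = (1+theta) * eps_tilde`, avoiding the
#'   degenerate CDF inverse. See [weitz_limit_environment()].
#' * `dist = "custom"`: a user-supplied strictly increasing quantile function
#'   `quantile_fn` (\eqn{F^{-1}}, defined on (0,1)); supports (even beyond
#'   `[0,1]`) are used as-is since the drift remains well defined.
#'
#' @param epsilon Relative speed of environmental dynamics, positive. For
#'   `dist = "heaviside"` supply `eps_tilde` instead.
#' @param dist One of `"uniform"`, `"heaviside"`, `"custom"`.
#' @param mu Center of the uniform threshold distribution.
#' @param a Width of the uniform threshold distribution, positive.
#' @param theta Environmental enhancement rate of the L strategy relative to
#'   degradation by H (Heaviside variant), positive.
#' @param eps_tilde Timescale of the Heaviside variant, positive.
#' @param quantile_fn Quantile function for `dist = "custom"`.
#' @return An environment object of class
#'   `c("tipping_environment", "eco_environment")`.
#' @export
tipping_environment <- function(epsilon = 1,
                                dist = c("uniform", "heaviside", "custom"),
                                mu = NULL, a = NULL, theta = NULL,
                                eps_tilde = NULL, quantile_fn = NULL) {
  dist <- match.arg(dist)
  env <- switch(dist,
    uniform = {
      if (is.null(mu) || is.null(a) || !(a > 0))
        stop("uniform tipping distribution needs `mu` and width `a` > 0",
             call. = FALSE)
      if (!(epsilon > 0)) stop("epsilon must be positive", call. = FALSE)
      list(dist = "uniform", mu = mu, a = a, epsilon = epsilon)
    },
    heaviside = {
      if (is.null(theta) || !(theta > 0))
        stop("heaviside tipping needs `theta` > 0", call. = FALSE)
      if (is.null(eps_tilde)) eps_tilde <- epsilon / (1 + theta)
      if (!(eps_tilde > 0)) stop("eps_tilde must be positive", call. = FALSE)
      list(dist = "heaviside", theta = theta, eps_tilde = eps_tilde,
           mu = 1 / (1 + theta), epsilon = (1 + theta) * eps_tilde)
    },
    custom = {
      if (!is.function(quantile_fn))
        stop("custom tipping needs a quantile function `quantile_fn`",
             call. = FALSE)
      if (!(epsilon > 0)) stop("epsilon must be positive", call. = FALSE)
      list(dist = "custom", quantile_fn = quantile_fn, epsilon = epsilon)
    })
  structure(env, class = c("tipping_environment", "eco_environment"))
}

#' Weitz-limit tipping environment
#'
#' The tipping-point model with a degenerate (zero-variance) threshold
#' distribution recovers the classic model without intrinsic environmental
#' dynamics, \eqn{dn/dt = \tilde\epsilon n(1-n)(\theta x - (1-x))}: it is the
#' `a -> 0` limit of the uniform case with tipping point `mu = 1/(1+theta)`
#' and timescale `epsilon = (1+theta) * eps_tilde`.
#'
#' @param theta Enhancement rate, positive.
#' @param eps_tilde Timescale, positive.
#' @return A Heaviside [tipping_environment()].
#' @export
weitz_limit_environment <- function(theta, eps_tilde = 1) {
  if (!is.numeric(theta) || !(theta > 0))
    stop("theta must be positive", call. = FALSE)
  if (!(eps_tilde > 0)) stop("eps_tilde must be positive", call. = FALSE)
  tipping_environment(dist = "heaviside", theta = theta,
                      eps_tilde = eps_tilde)
}

#' Environmental drift dn/dt
#'
#' Evaluates the intrinsic-plus-impact environmental dynamics of an
#' environment object at strategy frequency `x` and state `n`.
#'
#' @param env An [eco environment][renewing_resource()].
#' @param x Strategy frequency in `[0, 1]` (vectorized).
#' @param n Environmental state in `[0, 1]` (vectorized).
#' @return `dn/dt` (1/time), same length as `x`/`n` after recycling.
#' @export
env_drift <- function(env, x, n) {
  if (!inherits(env, "eco_environment"))
    stop("`env` must be an eco_environment", call. = FALSE)
  check_unit(x, "x")
  check_unit(n, "n")
  UseMethod("env_drift")
}

#' @export
env_drift.renewing_resource <- function(env, x, n) {
  env$epsilon * (env$r - env$q * (env$eL * n + env$eH * (1 - n))) * (x - n)
}

#' @export
env_drift.decaying_resource <- function(env, x, n) {
  env$epsilon * env$alpha * (x - n)
}

#' @export
env_drift.tipping_environment <- function(env, x, n) {
  switch(env$dist,
    uniform = env$epsilon * n * (1 - n) * (x - env$a * n + env$a / 2 - env$mu),
    heaviside = env$eps_tilde * n * (1 - n) * (env$theta * x - (1 - x)),
    custom = {
      d <- numeric(length(n))
      interior <- n > 0 & n < 1
      # n(1-n) factor kills the drift on the invariant edges regardless of F^-1
      if (any(interior)) {
        d[interior] <- env$epsilon * n[interior] * (1 - n[interior]) *
          (rep_len(x, length(n))[interior] - env$quantile_fn(n[interior]))
      }
      d
    })
}

# partial derivatives of dn/dt, for the closed-form Jacobian
env_drift_dx <- function(env, x, n) UseMethod("env_drift_dx")
#' @export
env_drift_dx.renewing_resource <- function(env, x, n) {
  env$epsilon * (env$r - env$q * (env$eL * n + env$eH * (1 - n)))
}
#' @export
env_drift_dx.decaying_resource <- function(env, x, n) env$epsilon * env$alpha
#' @export
env_drift_dx.tipping_environment <- function(env, x, n) {
  switch(env$dist,
    uniform = env$epsilon * n * (1 - n),
    heaviside = env$eps_tilde * n * (1 - n) * (env$theta + 1),
    custom = env$epsilon * n * (1 - n))
}

env_drift_dn <- function(env, x, n) UseMethod("env_drift_dn")
#' @export
env_drift_dn.renewing_resource <- function(env, x, n) {
  bracket <- env$r - env$q * (env$eL * n + env$eH * (1 - n))
  env$epsilon * (env$q * (env$eH - env$eL) * (x - n) - bracket)
}
#' @export
env_drift_dn.decaying_resource <- function(env, x, n) -env$epsilon * env$alpha
#' @export
env_drift_dn.tipping_environment <- function(env, x, n) {
  switch(env$dist,
    uniform = env$epsilon * ((1 - 2 * n) * (x - env$a * n + env$a / 2 - env$mu)
                             - n * (1 - n) * env$a),
    heaviside = env$eps_tilde * (1 - 2 * n) * (env$theta * x - (1 - x)),
    custom = stop("no closed-form derivative for custom tipping CDFs",
                  call. = FALSE))
}

#' Raw stock to normalized environmental state, and back
#'
#' The raw resource stock `m` of a renewing or decaying environment is mapped
#' to the normalized state `n` in `[0, 1]` by the affine transformation that
#' sends the steady-state stock under pure high-impact play to `n = 0` and
#' under pure low-impact play to `n = 1`:
#' * renewing: `m_L* = k (1 - q eL / r)`, `m_H* = k (1 - q eH / r)`,
#'   `n = (m - m_H*) / (m_L* - m_H*)` (more stock = richer state);
#' * decaying: `m_L* = eL / alpha`, `m_H* = eH / alpha`,
#'   `n = (m_H* - m) / (m_H* - m_L*)` (less pollutant = cleaner state).
#'
#' Differentiating this transform along the raw-stock dynamics reproduces the
#' normalized drift of [env_drift()] exactly on the `m = m(n)` manifold.
#'
#' @param env A [renewing_resource()] or [decaying_resource()] (the latter
#'   must carry emission rates `eL`, `eH`).
#' @param m Raw stock, non-negative (vectorized).
#' @param n Normalized state (vectorized).
#' @return `stock_to_state()` returns `n`; `state_to_stock()` returns `m`.
#'   The two maps are mutually inverse.
#' @export
stock_to_state <- function(env, m) {
  ms <- steady_stocks(env)
  if (inherits(env, "renewing_resource")) {
    (m - ms["H"]) / (ms["L"] - ms["H"])
  } else {
    (ms["H"] - m) / (ms["H"] - ms["L"])
  }
}

#' @rdname stock_to_state
#' @export
state_to_stock <- function(env, n) {
  ms <- steady_stocks(env)
  if (inherits(env, "renewing_resource")) {
    ms["H"] + n * (ms["L"] - ms["H"])
  } else {
    ms["H"] - n * (ms["H"] - ms["L"])
  }
}

steady_stocks <- function(env) {
  if (inherits(env, "renewing_resource")) {
    c(L = env$k * (1 - env$q * env$eL / env$r),
      H = env$k * (1 - env$q * env$eH / env$r))
  } else if (inherits(env, "decaying_resource")) {
    if (is.null(env$eL) || is.null(env$eH))
      stop("decaying environment carries no emission rates; ",
           "stock transforms are undefined", call. = FALSE)
    c(L = env$eL / env$alpha, H = env$eH / env$alpha)
  } else {
    stop("stock transforms are defined for renewing/decaying environments only",
         call. = FALSE)
  }
}

#' Raw-stock time derivative dm/dt
#'
#' The untransformed stock dynamics (logistic growth minus harvest for a
#' renewing resource; emission minus decay for a pollutant). Retained chiefly
#' as a verification oracle for the normalized dynamics.
#'
#' @inheritParams stock_to_state
#' @param x Strategy frequency in `[0, 1]`.
#' @return `dm/dt` in stock units per time.
#' @export
stock_drift <- function(env, x, m) {
  check_unit(x, "x")
  if (inherits(env, "renewing_resource")) {
    env$r * m * (1 - m / env$k) -
      env$q * m * (env$eL * x + env$eH * (1 - x))
  } else if (inherits(env, "decaying_resource")) {
    if (is.null(env$eL)) stop("no emission rates set", call. = FALSE)
    -env$alpha * m + env$eL * x + env$eH * (1 - x)
  } else {
    stop("raw stock dynamics are defined for renewing/decaying environments",
         call. = FALSE)
  }
}

#' @export
print.eco_environment <- function(x, ...) {
  if (inherits(x, "renewing_resource")) {
    cat(sprintf(
      "Renewing resource: r = %g, k = %g, q = %g, eL = %g, eH = %g, epsilon = %g\n",
      x$r, x$k, x$q, x$eL, x$eH, x$epsilon))
  } else if (inherits(x, "decaying_resource")) {
    cat(sprintf("Decaying resource: alpha = %g, epsilon = %g\n",
                x$alpha, x$epsilon))
  } else {
    cat(sprintf("Tipping-point environment (%s), epsilon = %g\n",
                x$dist, x$epsilon))
  }
  invisible(x)
}

#' JSON (de)serialization of environments
#'
#' @param env An environment object (custom tipping CDFs cannot be
#'   serialized).
#' @return `environment_to_json()` returns a JSON string;
#'   `environment_from_json()` its inverse from a string, file, or parsed
#'   list.
#' @export
environment_to_json <- function(env) {
  stopifnot(inherits(env, "eco_environment"))
  l <- if (inherits(env, "renewing_resource")) {
    c(type = "renewing", unclass(env))
  } else if (inherits(env, "decaying_resource")) {
    c(type = "decaying", unclass(env)[!vapply(unclass(env), is.null, TRUE)])
  } else {
    if (identical(env$dist, "custom"))
      stop("custom tipping environments cannot be serialized", call. = FALSE)
    c(type = "tipping", unclass(env))
  }
  jsonlite::toJSON(l, auto_unbox = TRUE, digits = NA)
}

#' @rdname environment_to_json
#' @param json JSON string, file path, or an already-parsed list.
#' @export
environment_from_json <- function(json) {
  l <- if (is.list(json)) json else jsonlite::fromJSON(json)
  if (is.null(l$type)) stop("environment block needs a `type`", call. = FALSE)
  switch(l$type,
    renewing = renewing_resource(r = l$r, k = l$k, q = l$q, eL = l$eL,
                                 eH = l$eH, epsilon = l$epsilon),
    decaying = decaying_resource(alpha = l$alpha, epsilon = l$epsilon,
                                 eL = l$eL, eH = l$eH),
    tipping = {
      if (identical(l$dist, "uniform"))
        tipping_environment(dist = "uniform", mu = l$mu, a = l$a,
                            epsilon = l$epsilon)
      else if (identical(l$dist, "heaviside"))
        tipping_environment(dist = "heaviside", theta = l$theta,
                            eps_tilde = l$eps_tilde)
      else stop("unknown tipping dist: ", l$dist, call. = FALSE)
    },
    stop("unknown environment type: ", l$type, call. = FALSE))
}
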