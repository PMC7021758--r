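#' Environment-dependent payoff structure
#'
#' Constructs the eight payoffs of a two-strategy game whose payoff matrix
#' interpolates linearly in the environmental state `n` between a poor-state
#' matrix (subscript 0, `n = 0`) and a rich-state matrix (subscript 1,
#' `n = 1`):
#' \deqn{\Pi(n) = (1-n)\begin{pmatrix}R_0 & S_0\\ T_0 & P_0\end{pmatrix} +
#'       n\begin{pmatrix}R_1 & S_1\\ T_1 & P_1\end{pmatrix}.}
#' Rows and columns are ordered (L, H), with L the low-impact strategy whose
#' frequency is `x` throughout the package.
#'
#' @param R0,S0,T0,P0 Payoffs under the poor environmental state (`n = 0`).
#' @param R1,S1,T1,P1 Payoffs under the rich environmental state (`n = 1`).
#' @return An object of class `"payoff_structure"`.
#' @seealso [incentive_params()], [incentives_from_payoffs()], [payoff_matrix()]
#' @examples
#' p <- payoff_structure(R0 = 3, S0 = 1, T0 = 0, P0 = 0,
#'                       R1 = -2, S1 = -1, T1 = 0, P1 = 0)
#' incentives_from_payoffs(p)
#' @export
payoff_structure <- function(R0, S0, T0, P0, R1, S1, T1, P1) {
  vals <- c(R0 = R0, S0 = S0, T0 = T0, P0 = P0,
            R1 = R1, S1 = S1, T1 = T1, P1 = P1)
  if (!is.numeric(vals) || length(vals) != 8L || !all(is.finite(vals)))
    stop("all eight payoff entries must be finite numbers", call. = FALSE)
  structure(as.list(vals), class = "payoff_structure")
}

#' Incentive parameters for behavioral change
#'
#' The four incentive parameters are payoff differences at the corners of the
#' strategy-environment state space; they completely determine the strategy
#' dynamics of a linear eco-evolutionary game:
#' * `deltaL1` -- incentive to *lead a gold rush*: switch to the high-impact
#'   strategy in a rich environment when everyone plays L (`T1 - R1`).
#' * `deltaH1` -- incentive to *follow a gold rush*: switch to high-impact in
#'   a rich environment when everyone already plays H (`P1 - S1`).
#' * `dL0` -- incentive to *follow an environmental movement*: switch to
#'   low-impact in a poor environment when everyone plays L (`R0 - T0`).
#' * `dH0` -- incentive to *lead an environmental movement*: switch to
#'   low-impact in a poor environment when everyone plays H (`S0 - P0`).
#'
#' @param deltaL1,deltaH1,dL0,dH0 Finite numeric incentives (dimensionless
#'   fitness differences). No sign constraint; the signs select the dynamical
#'   regime.
#' @return An object of class `"incentive_params"`.
#' @examples
#' incentive_params(deltaL1 = 2, deltaH1 = 1, dL0 = 3, dH0 = 1)
#' @export
incentive_params <- function(deltaL1, deltaH1, dL0, dH0) {
  vals <- c(deltaL1 = deltaL1, deltaH1 = deltaH1, dL0 = dL0, dH0 = dH0)
  if (!is.numeric(vals) || length(vals) != 4L || !all(is.finite(vals)))
    stop("all four incentive parameters must be finite numbers", call. = FALSE)
  structure(as.list(vals), class = "incentive_params")
}

#' Derive incentive parameters from a payoff structure
#'
#' @param p A [payoff_structure()].
#' @return An [incentive_params()] object with
#'   `deltaL1 = T1 - R1`, `deltaH1 = P1 - S1`, `dL0 = R0 - T0`,
#'   `dH0 = S0 - P0`.
#' @export
incentives_from_payoffs <- function(p) {
  if (!inherits(p, "payoff_structure"))
    stop("`p` must be a payoff_structure", call. = FALSE)
  incentive_params(deltaL1 = p$T1 - p$R1,
                   deltaH1 = p$P1 - p$S1,
                   dL0     = p$R0 - p$T0,
                   dH0     = p$S0 - p$P0)
}

#' A representative payoff structure for given incentives
#'
#' Infinitely many payoff structures share the same four incentive
#' parameters (replicator dynamics only see payoff differences). This
#' canonical representative zeroes the H row in both environmental states
#' (`T0 = P0 = T1 = P1 = 0`) and places the incentives in the L row, so that
#' [incentives_from_payoffs()] inverts it exactly.
#'
#' @param inc An [incentive_params()] object.
#' @return A [payoff_structure()] with `R0 = dL0`, `S0 = dH0`,
#'   `R1 = -deltaL1`, `S1 = -deltaH1`, remaining entries zero.
#' @export
canonical_payoffs <- function(inc) {
  if (!inherits(inc, "incentive_params"))
    stop("`inc` must be an incentive_params object", call. = FALSE)
  payoff_structure(R0 = inc$dL0, S0 = inc$dH0, T0 = 0, P0 = 0,
                   R1 = -inc$deltaL1, S1 = -inc$deltaH1, T1 = 0, P1 = 0)
}

#' Evaluate the interpolated payoff matrix at an environmental state
#'
#' @param p A [payoff_structure()].
#' @param n Environmental state in `[0, 1]`.
#' @return The 2x2 matrix `(1-n)*Pi0 + n*Pi1`, rows/columns ordered (L, H).
#' @export
payoff_matrix <- function(p, n) {
  if (!inherits(p, "payoff_structure"))
    stop("`p` must be a payoff_structure", call. = FALSE)
  check_unit(n, "n")
  m0 <- matrix(c(p$R0, p$T0, p$S0, p$P0), 2, 2,
               dimnames = list(c("L", "H"), c("L", "H")))
  m1 <- matrix(c(p$R1, p$T1, p$S1, p$P1), 2, 2,
               dimnames = list(c("L", "H"), c("L", "H")))
  (1 - n) * m0 + n * m1
}

#' Payoff advantage of the low-impact strategy
#'
#' The gain function `g(x, n)` is the fitness difference between the
#' low-impact and high-impact strategies at strategy frequency `x` and
#' environmental state `n`; it is the quantity that drives the replicator
#' dynamics `dx/dt = x (1 - x) g(x, n)`. For linear games,
#' \deqn{g(x,n) = (1-n)\,[x\,\delta_L^0 + (1-x)\,\delta_H^0] -
#'       n\,[x\,\Delta_L^1 + (1-x)\,\Delta_H^1],}
#' which is bilinear with corner values `g(1,1) = -deltaL1`,
#' `g(0,1) = -deltaH1`, `g(1,0) = dL0`, `g(0,0) = dH0`.
#'
#' @param x Frequency of the low-impact strategy, in `[0, 1]`. Vectorized.
#' @param n Environmental state in `[0, 1]`. Vectorized (recycled with `x`).
#' @param inc An [incentive_params()] object.
#' @return Numeric vector of gains.
#' @examples
#' inc <- incentive_params(2, 1, 3, 1)
#' gain(0, 0, inc)   # = dH0
#' gain(1, 1, inc)   # = -deltaL1
#' @export
gain <- function(x, n, inc) {
  if (!inherits(inc, "incentive_params"))
    stop("`inc` must be an incentive_params object", call. = FALSE)
  check_unit(x, "x")
  check_unit(n, "n")
  (1 - n) * (x * inc$dL0 + (1 - x) * inc$dH0) -
    n * (x * inc$deltaL1 + (1 - x) * inc$deltaH1)
}

# partial derivatives of the gain, used by the closed-form Jacobian
gain_dx <- function(x, n, inc) {
  (1 - n) * (inc$dL0 - inc$dH0) - n * (inc$deltaL1 - inc$deltaH1)
}
gain_dn <- function(x, n, inc) {
  -(x * inc$dL0 + (1 - x) * inc$dH0) - (x * inc$deltaL1 + (1 - x) * inc$deltaH1)
}

check_unit <- function(v, name) {
  if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  invisible(v)
}

#' @export
print.incentive_params <- function(x, ...) {
  cat("Incentive parameters (lead/follow strategy change):\n")
  cat(sprintf("  deltaL1 (lead gold rush)      = %g\n", x$deltaL1))
  cat(sprintf("  deltaH1 (follow gold rush)    = %g\n", x$deltaH1))
  cat(sprintf("  dL0     (follow env movement) = %g\n", x$dL0))
  cat(sprintf("  dH0     (lead env movement)   = %g\n", x$dH0))
  invisible(x)
}

#' @export
print.payoff_structure <- function(x, ...) {
  cat("Environment-dependent payoffs Pi(n) = (1-n) Pi0 + n Pi1\n")
  cat("Pi0 (poor, n = 0):\n")
  print(payoff_matrix(x, 0))
  cat("Pi1 (rich, n = 1):\n")
  print(payoff_matrix(x, 1))
  invisible(x)
}

#' JSON serialization of game objects
#'
#' @param x An [incentive_params()] or [payoff_structure()] object.
#' @return A JSON string (keys `deltaL1,deltaH1,dL0,dH0` resp. `R0,...,P1`).
#' @seealso [incentives_from_json()], [payoffs_from_json()]
#' @export
game_to_json <- function(x) {
  stopifnot(inherits(x, c("incentive_params", "payoff_structure")))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}

#' @rdname game_to_json
#' @param json A JSON string or file path.
#' @export
incentives_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  do.call(incentive_params, l[c("deltaL1", "deltaH1", "dL0", "dH0")])
}

#' @rdname game_to_json
#' @export
payoffs_from_json <- function(json) {
  l <- jsonlite::fromJSON(json)
  do.call(payoff_structure, l[c("R0", "S0", "T0", "P0", "R1", "S1", "T1", "P1")])
}
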