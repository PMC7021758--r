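#' Common-pool resource harvesting parameters
#'
#' A bioeconomic harvesting game: individuals harvest a logistically growing
#' stock with either low effort `eL` or high effort `eH`, and fitness is the
#' profit \eqn{\pi(e_i, \eta) = p q \eta e_i - w e_i} with price `p`,
#' harvest efficiency `q`, and marginal effort cost `w`. Because profit is
#' linear in the stock, this is a linear eco-evolutionary game with a
#' renewing resource.
#'
#' @param p Price per unit harvest, positive.
#' @param q Harvest efficiency (1/(effort time)), positive.
#' @param w Marginal cost per unit effort, positive.
#' @param eL,eH Efforts, `0 < eL < eH < r/q`.
#' @param r,k Resource growth rate and carrying capacity, positive.
#' @return An object of class `"common_pool_params"`.
#' @export
common_pool_params <- function(p, q, w, eL, eH, r, k) {
  vals <- c(p = p, q = q, w = w, eL = eL, eH = eH, r = r, k = k)
  if (!all(is.finite(vals)) || !all(vals > 0))
    stop("all common-pool parameters must be positive", call. = FALSE)
  if (!(eL < eH && eH < r / q))
    stop("efforts must satisfy eL < eH < r/q", call. = FALSE)
  structure(as.list(vals), class = "common_pool_params")
}

#' Incentive parameters of the common-pool harvesting game
#'
#' With steady-state stocks \eqn{\eta_L^* = k(1 - q e_L / r)} and
#' \eqn{\eta_H^* = k(1 - q e_H / r)} under pure low- and high-effort play,
#' the incentives are
#' \deqn{\Delta_L^1 = \Delta_H^1 = (p q \eta_L^* - w)(e_H - e_L), \qquad
#'       \delta_L^0 = \delta_H^0 = (w - p q \eta_H^*)(e_H - e_L).}
#' All four are positive exactly when profit is positive at the stock
#' reached under pure low-impact play and negative under pure high-impact
#' play. The output always sits exactly on the boundary
#' \eqn{\Delta_H^1 \delta_L^0 = \Delta_L^1 \delta_H^0} of the
#' cycle-permitting region: follower and leader incentives coincide, so no
#' positive feedback speed can produce cycles.
#'
#' @param cp A [common_pool_params()] object.
#' @return An [incentive_params()] object.
#' @export
common_pool_incentives <- function(cp) {
  stopifnot(inherits(cp, "common_pool_params"))
  etaL <- cp$k * (1 - cp$q * cp$eL / cp$r)
  etaH <- cp$k * (1 - cp$q * cp$eH / cp$r)
  d_rich <- (cp$p * cp$q * etaL - cp$w) * (cp$eH - cp$eL)
  d_poor <- (cp$w - cp$p * cp$q * etaH) * (cp$eH - cp$eL)
  incentive_params(deltaL1 = d_rich, deltaH1 = d_rich,
                   dL0 = d_poor, dH0 = d_poor)
}

#' Payoff structure of the common-pool harvesting game
#'
#' The alternative construction route: evaluate the profit function at the
#' normalized environmental state's stock level
#' \eqn{\eta(n) = \eta_H^* + n(\eta_L^* - \eta_H^*)} for each effort. Since
#' profit depends only on own effort and the stock, rows are constant:
#' `R_n = S_n = pi(eL, eta(n))` and `T_n = P_n = pi(eH, eta(n))`. Feeding
#' the result through [incentives_from_payoffs()] reproduces
#' [common_pool_incentives()] to machine precision.
#'
#' @param cp A [common_pool_params()] object.
#' @return A [payoff_structure()] object.
#' @export
common_pool_payoffs <- function(cp) {
  stopifnot(inherits(cp, "common_pool_params"))
  etaL <- cp$k * (1 - cp$q * cp$eL / cp$r)
  etaH <- cp$k * (1 - cp$q * cp$eH / cp$r)
  profit <- function(e, eta) cp$p * cp$q * eta * e - cp$w * e
  payoff_structure(
    R0 = profit(cp$eL, etaH), S0 = profit(cp$eL, etaH),
    T0 = profit(cp$eH, etaH), P0 = profit(cp$eH, etaH),
    R1 = profit(cp$eL, etaL), S1 = profit(cp$eL, etaL),
    T1 = profit(cp$eH, etaL), P1 = profit(cp$eH, etaL))
}

#' The renewing-resource environment of a common-pool system
#'
#' @param cp A [common_pool_params()] object.
#' @param epsilon Relative speed of resource dynamics.
#' @return A [renewing_resource()] environment.
#' @export
common_pool_environment <- function(cp, epsilon = 1) {
  renewing_resource(r = cp$r, k = cp$k, q = cp$q, eL = cp$eL, eH = cp$eH,
                    epsilon = epsilon)
}

#' Dynamical outcome of a common-pool harvesting system
#'
#' Under the canonical profit signs (positive profit at the pure-low-effort
#' stock, negative at the pure-high-effort stock) the system sits exactly on
#' the boundary of the cycle region: the interior equilibrium
#' `x-* = dL0 / (dL0 + deltaL1)` is stable for *every* positive feedback
#' speed, so the only possible outcome is a stable mix of low- and
#' high-effort harvesters, and [epsilon_crit()] is `NA`. Outside those
#' profit signs the generic [classify_regime()] applies without this
#' special-case guarantee.
#'
#' @param cp A [common_pool_params()] object.
#' @param epsilon Relative speed of resource dynamics.
#' @return An `"ecogame_regime"` report.
#' @export
common_pool_outcome <- function(cp, epsilon = 1) {
  stopifnot(inherits(cp, "common_pool_params"))
  inc <- common_pool_incentives(cp)
  env <- common_pool_environment(cp, epsilon)
  canonical <- inc$deltaL1 > 0 && inc$dH0 > 0
  if (!canonical) return(classify_regime(inc, env))
  eqs <- all_equilibria(ecogame(inc, env))
  structure(list(panel = "b", regime = "stable_coexistence",
                 epsilon = epsilon, epsilon_crit = NA_real_,
                 conditions = list(
                   deltaL1 = inc$deltaL1, dH0 = inc$dH0,
                   followers_sum = inc$deltaH1 + inc$dL0,
                   follower_product_margin = 0,
                   epsilon = epsilon, epsilon_crit = NA_real_),
                 equilibria = eqs,
                 note = paste("common-pool boundary case: leader and follower",
                              "incentives coincide, no cycles for any epsilon")),
            class = "ecogame_regime")
}

#' Susceptibility of grass-legume competition to cycles
#'
#' Competition between non-fixing grasses (the low nitrogen-emission
#' strategy, frequency `x`) and nitrogen-fixing legumes maps onto the
#' decaying-resource framework with soil nitrogen limitation as the
#' environmental state. Ecological invasion reasoning fixes sign and
#' ordering constraints on the incentives: all four positive (each species
#' invades the other's monomorphic state under its favored environment),
#' and leading is harder than following
#' (`deltaL1 < deltaH1`, `dH0 < dL0`). Jointly these imply
#' \eqn{\Delta_L^1 \delta_H^0 < \Delta_H^1 \delta_L^0}, placing the system
#' in the cycle-capable region: cycles then occur whenever the
#' nitrogen feedback is slow enough (`epsilon < epsilon_crit`).
#'
#' @param inc An [incentive_params()] object describing the competition.
#' @return A list with `susceptible` (logical), `checks` (named logical
#'   vector of the individual conditions), and `failed` (names of violated
#'   conditions).
#' @export
grass_legume_susceptibility <- function(inc) {
  stopifnot(inherits(inc, "incentive_params"))
  checks <- c(
    deltaL1_positive = inc$deltaL1 > 0,
    deltaH1_positive = inc$deltaH1 > 0,
    dL0_positive = inc$dL0 > 0,
    dH0_positive = inc$dH0 > 0,
    lead_below_follow_rich = inc$deltaL1 < inc$deltaH1,
    lead_below_follow_poor = inc$dH0 < inc$dL0)
  list(susceptible = all(checks), checks = checks,
       failed = names(checks)[!checks])
}
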