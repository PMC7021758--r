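#' Diagnose the long-run attractor of a trajectory
#'
#' Operational attractor detection from a computed trajectory: the first
#' `transient_fraction` of the time span is discarded, then
#' * `fixed_point` -- terminal vector-field norm below `1e-8`;
#' * `edge_state` -- terminal state within `1e-6` of a corner of the unit
#'   square (absorbed, but the field-norm criterion not yet met);
#' * `limit_cycle` -- successive local maxima of `x(t)` settle to a positive
#'   amplitude: peak-to-trough amplitude above `amplitude_floor` with
#'   relative drift below 1% across the last three detected periods;
#' * `undetermined` -- anything else, with an explanatory note. A too-short
#'   trajectory is never silently reported as a fixed point.
#'
#' Peak detection works on the sequence of local maxima of `x(t)` (sign
#' changes of the numerical derivative, refined by quadratic interpolation),
#' which stays robust when cycles hug the edges of the square; the period is
#' the mean spacing of the last peaks. When the diagnosis is undetermined
#' and `extend = TRUE`, the integration is resumed from the terminal state
#' with a doubled time span, at most three times.
#'
#' @param traj An `"ecogame_trajectory"` from [integrate_ecogame()].
#' @param transient_fraction Fraction of the span to discard (default 0.5).
#' @param amplitude_floor Smallest peak-to-trough `x` amplitude accepted as
#'   a cycle (default `1e-3`); separates damped foci from genuine cycles
#'   near a Hopf point.
#' @param extend Logical; automatically extend undetermined trajectories.
#' @return An object of class `"attractor_diagnosis"`: list with `kind`,
#'   `location` (fixed-point coordinates or cycle mean), `amplitude`,
#'   `period`, and `note`.
#' @export
diagnose_attractor <- function(traj, transient_fraction = 0.5,
                               amplitude_floor = 1e-3, extend = TRUE) {
  stopifnot(inherits(traj, "ecogame_trajectory"))
  for (round in 0:3) {
    d <- diagnose_once(traj, transient_fraction, amplitude_floor)
    if (d$kind != "undetermined" || !extend || round == 3) return(d)
    # resume from the terminal state over a doubled span
    np <- length(traj$times)
    span <- traj$times[np] * 2
    more <- tryCatch(
      integrate_ecogame(traj$sys, traj$xs[np], traj$ns[np], span,
                        rtol = traj$metadata$rtol, atol = traj$metadata$atol,
                        t_eval = seq(0, span, length.out = max(4000, 2 * np))),
      ecogames_solver_error = function(e) e$trajectory)
    traj <- more
  }
  d
}

diagnose_once <- function(traj, transient_fraction, amplitude_floor) {
  t <- traj$times; x <- traj$xs; n <- traj$ns
  np <- length(t)
  mk <- function(kind, location = c(NA_real_, NA_real_), amplitude = NA_real_,
                 period = NA_real_, note = NULL) {
    structure(list(kind = kind, location = location, amplitude = amplitude,
                   period = period, note = note),
              class = "attractor_diagnosis")
  }
  term <- c(x[np], n[np])
  fn <- field_norm(traj$sys, term[1], term[2])
  if (fn < 1e-8) return(mk("fixed_point", term))
  corner_d <- min(sqrt((term[1] - c(0, 1, 0, 1))^2 + (term[2] - c(0, 0, 1, 1))^2))
  if (corner_d < 1e-6) return(mk("edge_state", round(term)))
  if (np < 50) return(mk("undetermined", note = "trajectory too short"))
  keep <- t >= transient_fraction * t[np]
  tk <- t[keep]; xk <- x[keep]; nk <- n[keep]
  pk <- local_extrema(tk, xk, maxima = TRUE)
  tr <- local_extrema(tk, xk, maxima = FALSE)
  if (nrow(pk) < 4 || nrow(tr) < 3)
    return(mk("undetermined",
              note = "fewer than 4 post-transient oscillation peaks"))
  m <- min(nrow(pk), nrow(tr), 4)
  peaks <- utils::tail(pk, m); troughs <- utils::tail(tr, m)
  amps <- peaks$value - utils::tail(troughs$value, nrow(peaks))
  amplitude <- mean(amps)
  periods <- diff(peaks$time)
  period <- mean(periods)
  drift <- max(abs(amps - amplitude)) / max(amplitude, .Machine$double.eps)
  perdrift <- max(abs(periods - period)) / period
  if (amplitude > amplitude_floor && drift < 0.01 && perdrift < 0.05) {
    last_cycles <- tk >= peaks$time[1]
    return(mk("limit_cycle",
              location = c(mean(xk[last_cycles]), mean(nk[last_cycles])),
              amplitude = amplitude, period = period))
  }
  mk("undetermined", amplitude = amplitude, period = period,
     note = sprintf(
       "oscillation not settled (amplitude %.3g, drift %.2g%%)",
       amplitude, 100 * drift))
}

# interior local extrema of a sampled series, with quadratic refinement
local_extrema <- function(t, x, maxima = TRUE) {
  s <- if (maxima) x else -x
  i <- which(diff(sign(diff(s))) < 0) + 1L
  i <- i[i > 1 & i < length(s)]
  if (length(i) == 0) return(data.frame(time = numeric(0), value = numeric(0)))
  # quadratic through the three samples around each extremum
  t0 <- t[i - 1]; t1 <- t[i]; t2 <- t[i + 1]
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  denom <- (t0 - t1) * (t0 - t2) * (t1 - t2)
  a <- (t2 * (y1 - y0) + t1 * (y0 - y2) + t0 * (y2 - y1)) / denom
  b <- (t2^2 * (y0 - y1) + t1^2 * (y2 - y0) + t0^2 * (y1 - y2)) / denom
  tv <- ifelse(abs(a) > 0, -b / (2 * a), t1)
  ok <- tv >= t0 & tv <= t2 & is.finite(tv)
  tv[!ok] <- t1[!ok]
  c0 <- (y0 * t1 * t2 * (t1 - t2) + y1 * t0 * t2 * (t2 - t0) +
           y2 * t0 * t1 * (t0 - t1)) / denom
  vv <- a * tv^2 + b * tv + c0
  vv[!ok] <- y1[!ok]
  data.frame(time = tv, value = vv)
}

#' @export
print.attractor_diagnosis <- function(x, ...) {
  cat(sprintf("Attractor: %s", x$kind))
  if (x$kind %in% c("fixed_point", "edge_state"))
    cat(sprintf(" at (%.6g, %.6g)", x$location[1], x$location[2]))
  if (x$kind == "limit_cycle")
    cat(sprintf(" around (%.4g, %.4g); amplitude %.4g, period %.4g",
                x$location[1], x$location[2], x$amplitude, x$period))
  if (!is.null(x$note)) cat(" --", x$note)
  cat("\n")
  invisible(x)
}

#' Estimate basins of attraction on a grid
#'
#' Integrates from every interior point of a regular grid and diagnoses
#' each terminal attractor; fixed points are pooled when they agree to
#' `1e-3`, so each basin receives a stable label. Undetermined cells are
#' reported, not dropped. Deterministic given the configuration.
#'
#' @param sys An [ecogame()] system.
#' @param grid_resolution Interior points per axis (`>= 10`).
#' @param t_end Integration time per cell.
#' @param ... Passed to [integrate_ecogame()].
#' @return An object of class `"ecogame_basins"`: list with `labels`
#'   (a `grid_resolution` x `grid_resolution` character matrix, rows = `x0`,
#'   columns = `n0`), `inventory` (table of labels), `cells` (per-cell data
#'   frame), and `attractors` (one representative diagnosis per label).
#' @export
estimate_basins <- function(sys, grid_resolution = 10, t_end = 400, ...) {
  stopifnot(inherits(sys, "ecogame"))
  if (!(grid_resolution >= 10))
    stop("grid_resolution must be >= 10", call. = FALSE)
  u <- seq_len(grid_resolution) / (grid_resolution + 1)
  starts <- expand.grid(x0 = u, n0 = u)
  n_eval <- 4000
  diags <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    tr <- tryCatch(
      integrate_ecogame(sys, starts$x0[i], starts$n0[i], t_end,
                        t_eval = seq(0, t_end, length.out = n_eval), ...),
      ecogames_solver_error = function(e) e$trajectory)
    diags[[i]] <- diagnose_attractor(tr, extend = TRUE)
  }
  labels <- vapply(diags, attractor_label, character(1))
  cells <- data.frame(starts, label = labels)
  reps <- diags[!duplicated(labels)]
  names(reps) <- labels[!duplicated(labels)]
  structure(list(
    labels = matrix(labels, grid_resolution, grid_resolution,
                    dimnames = list(x0 = format(u, digits = 3),
                                    n0 = format(u, digits = 3))),
    inventory = table(label = labels),
    cells = cells,
    attractors = reps), class = "ecogame_basins")
}

attractor_label <- function(d) {
  switch(d$kind,
    fixed_point = sprintf("fp(%.3f,%.3f)", round(d$location[1], 3),
                          round(d$location[2], 3)),
    edge_state = sprintf("corner(%d,%d)", d$location[1], d$location[2]),
    limit_cycle = "cycle",
    "undetermined")
}

#' @export
print.ecogame_basins <- function(x, ...) {
  cat("Basins of attraction (share of grid cells):\n")
  print(round(x$inventory / sum(x$inventory), 3))
  invisible(x)
}
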