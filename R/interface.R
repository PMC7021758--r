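#' Read and validate a run configuration
#'
#' A run configuration is a JSON object (or equivalent R list) with fields
#' * exactly one of `incentives` (`deltaL1, deltaH1, dL0, dH0`) or
#'   `payoffs` (`R0 ... P1`);
#' * `environment`: a block with `type` in `renewing | decaying | tipping`
#'   and the class parameters, including `epsilon`;
#' * either `initial` (`x0`, `n0`) or `grid` (`resolution`) -- for
#'   simulation runs;
#' * optional `t_end`, `rtol`, `atol`, `seed`, and a `scan` block for
#'   [run_scan()].
#'
#' @param config A file path, JSON string, or list.
#' @return A validated configuration of class `"ecogame_config"`, with the
#'   parsed `incentives` and `environment` objects attached.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.list(config)) {
    config
  } else {
    txt <- if (length(config) == 1 && file.exists(config))
      paste(readLines(config, warn = FALSE), collapse = "\n") else config
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) {
               stop(errorCondition(
                 paste0("invalid JSON in run configuration: ",
                        conditionMessage(e)),
                 class = c("ecogames_config_json_error",
                           "ecogames_config_error", "error", "condition")))
             })
  }
  fail <- function(msg) stop(errorCondition(
    msg, class = c("ecogames_config_error", "error", "condition")))
  has_inc <- !is.null(cfg$incentives); has_pay <- !is.null(cfg$payoffs)
  if (has_inc == has_pay)
    fail("config must contain exactly one of `incentives` or `payoffs`")
  inc <- if (has_inc) {
    do.call(incentive_params,
            as.list(cfg$incentives)[c("deltaL1", "deltaH1", "dL0", "dH0")])
  } else {
    incentives_from_payoffs(do.call(payoff_structure, as.list(cfg$payoffs)))
  }
  if (is.null(cfg$environment)) fail("config must contain an `environment` block")
  env <- environment_from_json(as.list(cfg$environment))
  if (!is.null(cfg$initial)) {
    if (is.null(cfg$initial$x0) || is.null(cfg$initial$n0))
      fail("`initial` must carry x0 and n0")
  }
  cfg$t_end <- cfg$t_end %||% 200
  cfg$rtol <- cfg$rtol %||% 1e-9
  cfg$atol <- cfg$atol %||% 1e-9
  cfg$seed <- cfg$seed %||% 1L
  structure(c(cfg, list(.incentives = inc, .environment = env)),
            class = "ecogame_config")
}

config_fingerprint <- function(cfg) {
  core <- cfg[!startsWith(names(cfg), ".")]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(core, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

run_metadata <- function(cfg, extra = list()) {
  c(list(package = "ecogames",
         version = as.character(utils::packageVersion("ecogames")),
         solver = "dormand-prince-45",
         rtol = cfg$rtol, atol = cfg$atol, seed = cfg$seed,
         config_md5 = config_fingerprint(cfg)),
    extra)
}

#' Simulate a configured system and write the trajectory
#'
#' Integrates the configured system from its initial condition and writes a
#' CSV with header `t,x,n` plus a JSON metadata sidecar (solver, tolerances,
#' termination reason, seed, config hash).
#'
#' @param config Path, JSON string, or list (see [read_run_config()]).
#' @param out_csv Output CSV path.
#' @param meta_json Sidecar path (default: `out_csv` with `.meta.json`).
#' @return The trajectory, invisibly.
#' @export
run_simulate <- function(config, out_csv, meta_json = NULL) {
  cfg <- read_run_config(config)
  if (is.null(cfg$initial))
    stop(errorCondition("simulation config needs an `initial` block",
                        class = c("ecogames_config_error", "error",
                                  "condition")))
  if (is.null(meta_json))
    meta_json <- sub("\\.csv$", "", out_csv) |> paste0(".meta.json")
  sys <- ecogame(cfg$.incentives, cfg$.environment)
  traj <- integrate_ecogame(sys, cfg$initial$x0, cfg$initial$n0,
                            t_end = cfg$t_end, rtol = cfg$rtol,
                            atol = cfg$atol)
  utils::write.csv(as.data.frame(traj), out_csv, row.names = FALSE)
  meta <- run_metadata(cfg, list(termination = traj$metadata$termination,
                                 nsteps = traj$metadata$nsteps,
                                 t_end = cfg$t_end))
  jsonlite::write_json(meta, meta_json, auto_unbox = TRUE, digits = NA)
  invisible(traj)
}

#' Analyze a configured system: equilibria and dynamical regime
#'
#' Writes a TSV equilibrium table (columns `kind, x, n, re_eig1, im_eig1,
#' re_eig2, im_eig2, label`) and a JSON regime report including
#' `epsilon_crit` (`null` when no Hopf threshold exists). A degenerate
#' (continuum) game is reported with regime `boundary_degenerate` rather
#' than as an error.
#'
#' @param config Path, JSON string, or list.
#' @param out_tsv Equilibrium table path.
#' @param out_json Regime report path.
#' @return The regime report, invisibly.
#' @export
run_analyze <- function(config, out_tsv, out_json) {
  cfg <- read_run_config(config)
  reg <- classify_regime(cfg$.incentives, cfg$.environment)
  tab <- if (!is.null(reg$equilibria)) equilibria_table(reg$equilibria)
         else data.frame(kind = character(0), x = numeric(0), n = numeric(0),
                         re_eig1 = numeric(0), im_eig1 = numeric(0),
                         re_eig2 = numeric(0), im_eig2 = numeric(0),
                         label = character(0))
  utils::write.table(tab, out_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  report <- run_metadata(cfg, list(
    panel = reg$panel, regime = reg$regime, epsilon = reg$epsilon,
    epsilon_crit = if (is.na(reg$epsilon_crit)) NULL else reg$epsilon_crit,
    conditions = lapply(reg$conditions,
                        function(v) if (length(v) == 1 && is.na(v)) NULL else v),
    note = reg$note))
  jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(reg)
}

#' Scan a two-parameter slice of incentive space
#'
#' Classifies the dynamical regime over a rectangular grid in any two
#' incentive parameters (the remaining two and `epsilon` held fixed) and
#' writes one TSV row per cell: the grid coordinates, panel, regime, and
#' `epsilon_crit`. The scan is deterministic given the configuration, and
#' resumable: rows already present in `out_tsv` (matched by the two grid
#' values) are kept and not recomputed.
#'
#' The configuration must carry a `scan` block:
#' `{"param1": {"name": "deltaH1", "from": 0, "to": 4, "n": 9},
#'   "param2": {"name": "dL0", ...}}`, where names are incentive fields.
#'
#' @param config Path, JSON string, or list.
#' @param out_tsv Output (and cache) TSV path.
#' @return The scan table, invisibly.
#' @export
run_scan <- function(config, out_tsv) {
  cfg <- read_run_config(config)
  fail <- function(msg) stop(errorCondition(
    msg, class = c("ecogames_config_error", "error", "condition")))
  sc <- cfg$scan
  if (is.null(sc) || is.null(sc$param1) || is.null(sc$param2))
    fail("scan config needs `scan$param1` and `scan$param2`")
  fields <- c("deltaL1", "deltaH1", "dL0", "dH0")
  p1 <- sc$param1; p2 <- sc$param2
  if (!(p1$name %in% fields) || !(p2$name %in% fields))
    fail("scan parameters must name incentive fields")
  v1 <- seq(p1$from, p1$to, length.out = p1$n)
  v2 <- seq(p2$from, p2$to, length.out = p2$n)
  grid <- expand.grid(a = v1, b = v2)
  names(grid) <- c(p1$name, p2$name)
  key <- function(a, b) sprintf("%.12g|%.12g", a, b)
  cache <- if (file.exists(out_tsv)) {
    old <- utils::read.table(out_tsv, header = TRUE, sep = "\t")
    stats::setNames(seq_len(nrow(old)),
                    key(old[[p1$name]], old[[p2$name]]))
  } else NULL
  old <- if (!is.null(cache)) utils::read.table(out_tsv, header = TRUE,
                                                sep = "\t") else NULL
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    k <- key(grid[i, 1], grid[i, 2])
    if (!is.null(cache) && k %in% names(cache))
      return(old[cache[[k]], , drop = FALSE])
    inc <- cfg$.incentives
    inc[[p1$name]] <- grid[i, 1]
    inc[[p2$name]] <- grid[i, 2]
    row <- tryCatch({
      reg <- classify_regime(inc, cfg$.environment)
      data.frame(grid[i, 1], grid[i, 2], panel = reg$panel,
                 regime = reg$regime,
                 epsilon_crit = reg$epsilon_crit)
    }, error = function(e) {
      data.frame(grid[i, 1], grid[i, 2], panel = NA_character_,
                 regime = paste0("error: ", conditionMessage(e)),
                 epsilon_crit = NA_real_)
    })
    names(row)[1:2] <- c(p1$name, p2$name)
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  utils::write.table(out, out_tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(out)
}

#' Phase-plane plot of an eco-evolutionary system
#'
#' Draws the vector field of a system on the unit square together with its
#' nullclines and classified fixed points; optionally overlays trajectories.
#' A plotting convenience, not part of the analysis contracts.
#'
#' @param x An [ecogame()] system.
#' @param trajectories Optional list of `"ecogame_trajectory"` objects.
#' @param arrows Grid resolution of the direction field.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ecogame <- function(x, trajectories = NULL, arrows = 15, ...) {
  u <- seq(0.02, 0.98, length.out = arrows)
  gr <- expand.grid(x = u, n = u)
  f <- vector_field(x, gr$x, gr$n)
  len <- sqrt(f$dx^2 + f$dn^2)
  sc <- 0.35 / (arrows * stats::median(len[len > 0]))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "x (frequency of low-impact strategy)",
                 ylab = "n (environmental state)", ...)
  graphics::arrows(gr$x, gr$n, gr$x + f$dx * sc, gr$n + f$dn * sc,
                   length = 0.03, col = "grey60")
  graphics::abline(0, 1, lty = 2, col = "grey40")
  if (!is.null(trajectories)) {
    if (inherits(trajectories, "ecogame_trajectory"))
      trajectories <- list(trajectories)
    for (tr in trajectories)
      graphics::lines(tr$xs, tr$ns, col = "steelblue")
  }
  if (!inherits(x$environment, "tipping_environment")) {
    eqs <- tryCatch(all_equilibria(x), error = function(e) NULL)
    for (eq in eqs) {
      stable <- isTRUE(grepl("stable_", eq$label)) &&
        !grepl("^unstable", eq$label)
      graphics::points(eq$x_star, eq$n_star, pch = ifelse(stable, 19, 21),
                       bg = "white", cex = 1.3)
    }
  }
  invisible(x)
}

#' @export
plot.ecogame_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$xs, x$ns), type = "l", lty = 1,
                    col = c("steelblue", "darkgreen"),
                    xlab = "time", ylab = "state", ...)
  graphics::legend("topright", legend = c("x", "n"), lty = 1,
                   col = c("steelblue", "darkgreen"), bty = "n")
  invisible(x)
}
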