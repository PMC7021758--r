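demo_config <- function(eps = 0.2, x0 = 0.9, n0 = 0.6, t_end = 2000) {
  list(incentives = list(deltaL1 = 2, deltaH1 = 1, dL0 = 3, dH0 = 1),
       environment = list(type = "decaying", alpha = 1, epsilon = eps),
       initial = list(x0 = x0, n0 = n0), t_end = t_end, seed = 1)
}

test_that("configurations are validated with informative errors", {
  expect_error(read_run_config(list(environment = list(type = "decaying",
                                                       alpha = 1,
                                                       epsilon = 1))),
               class = "ecogames_config_error")
  both <- demo_config()
  both$payoffs <- list(R0 = 1, S0 = 0, T0 = 0, P0 = 0,
                       R1 = 0, S1 = 0, T1 = 0, P1 = 0)
  expect_error(read_run_config(both), "exactly one")
  noenv <- demo_config(); noenv$environment <- NULL
  expect_error(read_run_config(noenv), "environment")
  expect_error(read_run_config('{"incentives": {'),
               class = "ecogames_config_json_error")

  cfg <- read_run_config(demo_config())
  expect_s3_class(cfg$.incentives, "incentive_params")
  expect_s3_class(cfg$.environment, "decaying_resource")

  # payoff-specified config reduces to incentives
  pay <- demo_config(); pay$incentives <- NULL
  pay$payoffs <- list(R0 = 3, S0 = 1, T0 = 0, P0 = 0,
                      R1 = -2, S1 = -1, T1 = 0, P1 = 0)
  cfg2 <- read_run_config(pay)
  expect_equal(cfg2$.incentives, incentive_params(2, 1, 3, 1))
})

test_that("run_simulate writes the trajectory and metadata sidecar", {
  out <- tempfile(fileext = ".csv")
  run_simulate(demo_config(eps = 0.2), out)
  tab <- read.csv(out)
  expect_named(tab, c("t", "x", "n"))
  # high feedback speed: settles at the interior equilibrium 1/sqrt(3)
  expect_equal(tab$x[nrow(tab)], 0.57735, tolerance = 1e-4)
  meta <- jsonlite::fromJSON(sub("\\.csv$", ".meta.json", out))
  expect_equal(meta$solver, "dormand-prince-45")
  expect_true(meta$termination %in% c("t_end", "converged"))
  expect_true(nzchar(meta$config_md5))

  # corner start: constant file
  out2 <- tempfile(fileext = ".csv")
  run_simulate(demo_config(x0 = 1, n0 = 1, t_end = 10), out2)
  tab2 <- read.csv(out2)
  expect_true(all(tab2$x == 1) && all(tab2$n == 1))
})

test_that("run_analyze reports equilibria and the regime", {
  cfg <- demo_config(eps = 0.3)
  cfg$incentives <- list(deltaL1 = -1/8, deltaH1 = 4, dL0 = 1, dH0 = 2)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  run_analyze(cfg, tsv, js)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$label[tab$kind == "interior_plus"], "saddle")
  rep <- jsonlite::fromJSON(js)
  expect_equal(rep$panel, "c")
  expect_equal(rep$regime, "bistable_edge_interior")

  # panel-a config
  cfg$incentives <- list(deltaL1 = -1, deltaH1 = 1, dL0 = 1, dH0 = -1)
  run_analyze(cfg, tsv, js)
  expect_equal(jsonlite::fromJSON(js)$regime, "bistable_edges")

  # common-pool boundary: epsilon_crit absent (null) in the report
  cp <- common_pool_params(p = 1, q = 1, w = 0.6, eL = 0.1, eH = 0.5,
                           r = 1, k = 1)
  cfg$incentives <- unclass(common_pool_incentives(cp))
  cfg$environment <- list(type = "renewing", r = 1, k = 1, q = 1,
                          eL = 0.1, eH = 0.5, epsilon = 0.5)
  run_analyze(cfg, tsv, js)
  rep <- jsonlite::fromJSON(js)
  expect_null(rep$epsilon_crit)
})

test_that("run_scan maps the cycle region of a panel-b slice", {
  cfg <- demo_config()
  cfg$initial <- NULL
  cfg$incentives <- list(deltaL1 = 1, deltaH1 = 1, dL0 = 1, dH0 = 1)
  cfg$environment$epsilon <- 0.02
  cfg$scan <- list(param1 = list(name = "deltaH1", from = 0.5, to = 3, n = 6),
                   param2 = list(name = "dL0", from = 0.5, to = 3, n = 6))
  tsv <- tempfile(fileext = ".tsv")
  scan <- run_scan(cfg, tsv)
  expect_equal(nrow(scan), 36)
  cyc <- scan$regime == "limit_cycle"
  margin <- scan$deltaH1 * scan$dL0 - 1   # deltaL1 * dH0 = 1 on this slice
  # cycles exactly where the follower product exceeds the leader product and
  # the feedback is slower than the local threshold
  expect_equal(cyc, margin > 1e-9 & !is.na(scan$epsilon_crit) &
                 0.02 < scan$epsilon_crit)
  expect_true(any(cyc) && any(!cyc))

  # rerun from cache: byte-identical output
  first <- readLines(tsv)
  run_scan(cfg, tsv)
  expect_identical(readLines(tsv), first)
})

test_that("the command-line wrappers run end to end", {
  cli <- system.file("cli", "ecogame-simulate.R", package = "ecogames")
  expect_true(nzchar(cli))
  cfgfile <- tempfile(fileext = ".json")
  jsonlite::write_json(demo_config(eps = 0.2, t_end = 500), cfgfile,
                       auto_unbox = TRUE, digits = NA)
  out <- tempfile(fileext = ".csv")
  res <- system2("Rscript", c(cli, "--config", cfgfile, "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status") %||% 0, 0)
  expect_true(file.exists(out))

  # malformed JSON: exit code 2 and a parse message
  bad <- tempfile(fileext = ".json")
  writeLines('{"incentives": {', bad)
  res <- suppressWarnings(
    system2("Rscript", c(cli, "--config", bad, "--out", out),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res, "status"), 2)
  expect_match(paste(res, collapse = "\n"), "JSON", ignore.case = TRUE)
})
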