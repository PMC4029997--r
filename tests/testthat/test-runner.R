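toy_cfg <- function(mode, seed = 5, n_rounds = 400, ...) {
  dw <- double_well_model(5, 1, dim = 2)
  pr <- dynamics_params(dt = 0.02, gamma = 1, lam = 1, t_l = 1)
  run_config(dw, mode, 1, 5, 6, pr, steps_per_swap = 10,
             n_rounds = n_rounds, seed = seed, init_x = 1, ...)
}

test_that("static mode keeps one unique ladder for the whole run", {
  res <- run_simulation(toy_cfg("static"))
  expect_length(res$ladder_history$ladders, 1)
  expect_equal(res$ladder_history$ladders[[1]]$temps,
               geometric_ladder(1, 5, 6)$temps)
})

test_that("adaptive mode: final ladder differs from geometric, satisfies the constraint", {
  res <- run_simulation(toy_cfg("adaptive", n_rounds = 1500))
  expect_gt(length(res$ladder_history$ladders), 1)
  geo <- geometric_ladder(1, 5, 6)
  fin <- res$rep$ladder
  expect_gt(max(abs(fin$temps - geo$temps)), 1e-6)
  r <- spacing_ratio(geo)
  for (lad in res$ladder_history$ladders) {
    expect_identical(lad$temps[1], 1)
    expect_identical(lad$temps[6], 5)
    expect_lte(max(lad$temps[-1] / lad$temps[-6]), r^2 * (1 + 1e-12))
    expect_true(all(diff(lad$temps) > 0))
  }
})

test_that("same config and seed reproduce identical artifacts byte-for-byte", {
  res1 <- run_simulation(toy_cfg("adaptive", seed = 21))
  res2 <- run_simulation(toy_cfg("adaptive", seed = 21))
  expect_identical(res1$occupancy, res2$occupancy)
  expect_identical(res1$energies, res2$energies)
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  write_run_artifacts(res1, d1)
  write_run_artifacts(res2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("compiled and modular run paths agree exactly on a shared seed", {
  cfg <- toy_cfg("adaptive", seed = 31, n_rounds = 300)
  a <- run_simulation(cfg, use_compiled = TRUE)
  b <- run_simulation(cfg, use_compiled = FALSE)
  expect_identical(a$occupancy, b$occupancy)
  expect_identical(a$rep$round_trips, b$rep$round_trips)
  expect_equal(a$rep$ladder$temps, b$rep$ladder$temps, tolerance = 1e-12)
  expect_equal(a$energies, b$energies, tolerance = 1e-12)
  expect_identical(a$rep$label, b$rep$label)
})

test_that("replay closure: stats re-derivable from the occupancy trace", {
  res <- run_simulation(toy_cfg("adaptive", seed = 41, n_rounds = 1000))
  replay <- replay_occupancy(res$occupancy)
  expect_equal(replay$round_trips, res$rep$round_trips)
  expect_equal(replay$n_cold, res$hist$n_cold)
  expect_equal(replay$n_hot, res$hist$n_hot)
  # exchange-rate totals consistent: every pair attempted every other round
  expect_equal(sum(res$rep$attempts),
               sum(vapply(1:1000, function(k)
                 length(seq.int(1 + k %% 2, 5, by = 2)), numeric(1))))
})

test_that("compare_modes: validation and identical-mode null result", {
  cfg_a <- toy_cfg("static", n_rounds = 200)
  cfg_b <- toy_cfg("static", n_rounds = 200)
  cmp <- compare_modes(cfg_a, cfg_b, seeds = c(3, 4))
  expect_equal(cmp$round_trips_a, cmp$round_trips_b)   # same runs exactly
  expect_equal(cmp$mean_a - cmp$mean_b, 0)
  cfg_c <- toy_cfg("adaptive", n_rounds = 100)
  expect_error(compare_modes(cfg_a, cfg_c), "differ")
  # model mismatch caught
  cfg_d <- cfg_b
  cfg_d$model <- harmonic_model(1, 2)
  expect_error(compare_modes(cfg_a, cfg_d, seeds = 1), "differ")
})

test_that("run artifacts round-trip through the CSV logs", {
  res <- run_simulation(toy_cfg("adaptive", seed = 51, n_rounds = 600))
  d <- file.path(tempdir(), "runC")
  write_run_artifacts(res, d)
  occ <- utils::read.csv(file.path(d, "occupancy.csv"))
  occ_mat <- matrix(occ$window_index[order(occ$step, occ$replica_id)],
                    ncol = 6, byrow = TRUE)
  expect_equal(occ_mat, unname(res$occupancy))
  hb <- read_histogram_csv(file.path(d, "histogram.csv"))
  expect_equal(hb$hist$n_cold, res$hist$n_cold)
  expect_equal(hb$ladder$temps, res$rep$ladder$temps, tolerance = 1e-10)
  rates <- utils::read.csv(file.path(d, "exchange_rates.csv"))
  expect_equal(rates$attempts, res$rep$attempts)
  summ <- jsonlite::read_json(file.path(d, "summary.json"))
  expect_equal(summ$seed, 51)
  expect_equal(summ$mode, "adaptive")
  unlink(d, recursive = TRUE)
})

test_that("CLI round-trips a tiny run and offline ladder adaptation", {
  cli <- system.file("cli", "adaptrex.R", package = "adaptrex")
  rscript <- file.path(R.home("bin"), "Rscript")
  td <- file.path(tempdir(), "cli_run")
  cfg <- list(model = list(kind = "double_well", barrier = 5, x0 = 1, dim = 2),
              mode = "adaptive", t_min = 1, t_max = 5, n = 4, dt = 0.02,
              gamma = 1, lam = 1, t_l = 1, steps_per_swap = 10,
              n_rounds = 300, seed = 7, init_x = 1, out_dir = td)
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  out <- system2(rscript, c(cli, "run", cfg_path), stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status"), NULL)
  expect_true(file.exists(file.path(td, "occupancy.csv")))
  # offline adaptation consumes the emitted histogram
  lad_out <- tempfile(fileext = ".csv")
  out2 <- system2(rscript, c(cli, "adapt-ladder",
                             file.path(td, "histogram.csv"), lad_out),
                  stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out2, "status"), NULL)
  lad <- read_ladder_csv(lad_out)
  expect_equal(lad$t_min, 1)
  expect_equal(lad$t_max, 5)
  unlink(c(td, cfg_path, lad_out), recursive = TRUE)
})
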