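#' Run configuration and orchestration of replica-exchange simulations
#'
#' A run alternates dynamics segments with Metropolis swap rounds
#' (even/odd neighbor parity alternating), updates walker labels and the
#' cold/hot visit histogram after every round, and — in adaptive mode —
#' periodically re-places the ladder temperatures from the accumulated
#' fraction-cold profile. Everything is reproducible bit-for-bit from the
#' seed.
#'
#' @name cli_runner
NULL

#' Build a validated run configuration
#'
#' @param model an \code{energy_model}.
#' @param mode \code{"static"} or \code{"adaptive"} ladder.
#' @param t_min,t_max,n ladder bounds and client count.
#' @param params a \code{dynamics_params}.
#' @param steps_per_swap integrator steps per swap attempt (500 at
#'   dt = 2 fs reproduces the 1 ps physical exchange cadence).
#' @param n_rounds total swap rounds.
#' @param seed mandatory RNG seed.
#' @param adapt_interval swap rounds between ladder updates (adaptive mode).
#' @param adapt_min_visits labeled visits both extreme windows must have
#'   before the first update (avoids inverting an all-undefined profile).
#' @param reset_hist_on_adapt reset histograms after each ladder update
#'   (default FALSE: cumulative accumulation).
#' @param rescale_momenta rescale momenta (and momentum memory) by
#'   sqrt(T_new/T_old) when a replica changes window.
#' @param init_x initial coordinates (recycled per replica), default zeros.
#' @return an object of class \code{run_config}.
#' @export
run_config <- function(model, mode = c("static", "adaptive"), t_min, t_max, n,
                       params, steps_per_swap = 500L, n_rounds = 1000L,
                       seed, adapt_interval = 100L, adapt_min_visits = 10L,
                       reset_hist_on_adapt = FALSE, rescale_momenta = TRUE,
                       init_x = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "energy_model"), inherits(params, "dynamics_params"))
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (steps_per_swap < 1L || n_rounds < 1L) stop("invalid run lengths")
  if (is.null(init_x)) init_x <- numeric(model$dim)
  init_x <- rep_len(as.numeric(init_x), model$dim)
  structure(list(model = model, mode = mode, t_min = t_min, t_max = t_max,
                 n = as.integer(n), params = params,
                 steps_per_swap = as.integer(steps_per_swap),
                 n_rounds = as.integer(n_rounds), seed = as.integer(seed),
                 adapt_interval = as.integer(adapt_interval),
                 adapt_min_visits = as.integer(adapt_min_visits),
                 reset_hist_on_adapt = isTRUE(reset_hist_on_adapt),
                 rescale_momenta = isTRUE(rescale_momenta),
                 init_x = init_x),
            class = "run_config")
}

#' Execute a replica-exchange run
#'
#' @param config a \code{run_config}.
#' @param use_compiled passed to \code{\link{run_segment}}.
#' @return an object of class \code{run_result}: \code{rep} (final
#'   \code{replica_set}), \code{hist} (\code{visit_histogram}),
#'   \code{occupancy} (n_rounds x n matrix, window of each replica after
#'   each round), \code{energies} (n_rounds x n, per-window potential energy
#'   at the swap test), \code{ladder_history} (\code{times} in rounds +
#'   \code{ladders}), \code{config}.
#' @export
run_simulation <- function(config,
                           use_compiled = getOption("adaptrex.compiled", TRUE)) {
  stopifnot(inherits(config, "run_config"))
  if (use_compiled && .compiled_model_id(config$model) > 0L)
    .run_sim_compiled(config)
  else
    .run_sim_modular(config, use_compiled = FALSE)
}

# chunked compiled loop: C++ advances whole swap rounds (drawing from the R
# RNG in the modular path's order); R handles ladder adaptation between
# chunks, so both paths are bit-identical on a shared seed
.run_sim_compiled <- function(config) {
  set.seed(config$seed)
  ladder <- geometric_ladder(config$t_min, config$t_max, config$n)
  n <- ladder$n
  d <- config$model$dim
  X <- matrix(rep(config$init_x, n), d, n)
  P <- matrix(0, d, n)
  PA <- matrix(0, d, n)
  window_of <- seq_len(n)
  replica_in <- seq_len(n)
  label <- integer(n)
  attempts <- numeric(n - 1L)
  accepts <- numeric(n - 1L)
  round_trips <- numeric(n)
  n_cold <- numeric(n)
  n_hot <- numeric(n)
  occ <- matrix(NA_integer_, config$n_rounds, n)
  ener <- matrix(NA_real_, config$n_rounds, n)
  lad_times <- 0
  lad_list <- list(ladder)
  masses <- .dof_masses(config$params, d)
  mpar <- unname(config$model$params)
  mid <- .compiled_model_id(config$model)

  done <- 0L
  chunk_len <- if (config$mode == "adaptive") config$adapt_interval else
    config$n_rounds
  while (done < config$n_rounds) {
    k <- min(chunk_len, config$n_rounds - done)
    out <- cpp_run_rounds(X, P, PA, window_of, replica_in, label,
                          attempts, accepts, round_trips, n_cold, n_hot,
                          ladder$temps, masses, config$params$dt,
                          config$params$gamma, config$params$lam,
                          config$params$t_l, config$params$kB,
                          config$steps_per_swap, k, done, mid, mpar,
                          config$rescale_momenta)
    occ[(done + 1L):(done + k), ] <- out$occupancy
    ener[(done + 1L):(done + k), ] <- out$energies
    done <- done + k
    if (config$mode == "adaptive" && done %% config$adapt_interval == 0L) {
      if (n_cold[1L] + n_hot[1L] >= config$adapt_min_visits &&
          n_cold[n] + n_hot[n] >= config$adapt_min_visits) {
        old_temps <- ladder$temps
        ladder <- adapt_temperatures(ladder, visit_histogram(n_cold, n_hot))
        if (config$rescale_momenta) {
          sc <- sqrt(ladder$temps[window_of] / old_temps[window_of])
          P <- sweep(P, 2L, sc, `*`)
          PA <- sweep(PA, 2L, sc, `*`)
        }
        if (config$reset_hist_on_adapt) {
          n_cold <- numeric(n)
          n_hot <- numeric(n)
        }
        lad_times <- c(lad_times, done)
        lad_list <- c(lad_list, list(ladder))
      }
    }
  }
  rep <- replica_set(ladder, kB = config$params$kB)
  rep$window_of <- as.integer(window_of)
  rep$replica_in <- as.integer(replica_in)
  rep$label <- c("unlabeled", "cold", "hot")[label + 1L]
  rep$attempts <- attempts
  rep$accepts <- accepts
  rep$round_trips <- round_trips
  structure(list(rep = rep, hist = visit_histogram(n_cold, n_hot),
                 occupancy = occ, energies = ener,
                 ladder_history = list(times = lad_times, ladders = lad_list),
                 config = config),
            class = "run_result")
}

.run_sim_modular <- function(config, use_compiled = FALSE) {
  set.seed(config$seed)
  ladder <- geometric_ladder(config$t_min, config$t_max, config$n)
  n <- ladder$n
  rep <- replica_set(ladder, kB = config$params$kB)
  hist <- visit_histogram(numeric(n), numeric(n))
  states <- lapply(seq_len(n), function(i) replica_dyn_state(config$init_x))
  occupancy <- matrix(NA_integer_, config$n_rounds, n)
  energies <- matrix(NA_real_, config$n_rounds, n)
  lad_times <- 0
  lad_list <- list(ladder)

  for (round in seq_len(config$n_rounds)) {
    temps <- rep$ladder$temps
    e_win <- numeric(n)
    for (r in seq_len(n)) {
      w <- rep$window_of[r]
      seg <- run_segment(states[[r]], config$model, temps[w], config$params,
                         config$steps_per_swap, use_compiled = use_compiled)
      states[[r]] <- seg$state
      e_win[w] <- seg$e_pot
    }
    win_before <- rep$window_of
    parity <- if (round %% 2L == 1L) "even" else "odd"
    rep <- attempt_swaps(rep, e_win, parity)
    if (config$rescale_momenta) {
      moved <- which(rep$window_of != win_before)
      for (r in moved) {
        sc <- sqrt(temps[rep$window_of[r]] / temps[win_before[r]])
        states[[r]]$p <- states[[r]]$p * sc
        states[[r]]$p_avg <- states[[r]]$p_avg * sc
      }
    }
    rep <- update_walker_labels(rep)
    hist <- record_visits(rep, hist)
    occupancy[round, ] <- rep$window_of
    energies[round, ] <- e_win

    if (config$mode == "adaptive" && round %% config$adapt_interval == 0L) {
      tot1 <- hist$n_cold[1L] + hist$n_hot[1L]
      totn <- hist$n_cold[n] + hist$n_hot[n]
      if (tot1 >= config$adapt_min_visits && totn >= config$adapt_min_visits) {
        old_temps <- rep$ladder$temps
        new_lad <- adapt_temperatures(rep$ladder, hist)
        rep$ladder <- new_lad
        if (config$rescale_momenta) {
          for (r in seq_len(n)) {
            w <- rep$window_of[r]
            sc <- sqrt(new_lad$temps[w] / old_temps[w])
            states[[r]]$p <- states[[r]]$p * sc
            states[[r]]$p_avg <- states[[r]]$p_avg * sc
          }
        }
        if (config$reset_hist_on_adapt)
          hist <- visit_histogram(numeric(n), numeric(n))
        lad_times <- c(lad_times, round)
        lad_list <- c(lad_list, list(new_lad))
      }
    }
  }
  structure(list(rep = rep, hist = hist, occupancy = occupancy,
                 energies = energies,
                 ladder_history = list(times = lad_times, ladders = lad_list),
                 config = config),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> mode = %s, %d rounds, %d replicas\n",
              x$config$mode, x$config$n_rounds, x$config$n))
  cat(sprintf("  mean round trips/replica: %.2f\n", mean(x$rep$round_trips)))
  cat(sprintf("  mean exchange rate: %.3f\n",
              mean(exchange_rate_profile(x$rep), na.rm = TRUE)))
  invisible(x)
}

#' Recount round trips and visit histograms from an occupancy trace
#'
#' Independent replay of the label/round-trip bookkeeping from the saved
#' window-index series; used to close the loop between live statistics and
#' raw logs.
#'
#' @param occupancy n_rounds x n matrix of window indices (1-based).
#' @return list with \code{round_trips} (per replica), \code{n_cold},
#'   \code{n_hot} (per window).
#' @export
replay_occupancy <- function(occupancy) {
  n <- ncol(occupancy)
  n_win <- max(occupancy)
  label <- rep("unlabeled", n)
  rt <- numeric(n)
  n_cold <- numeric(n_win)
  n_hot <- numeric(n_win)
  for (round in seq_len(nrow(occupancy))) {
    w <- occupancy[round, ]
    for (r in seq_len(n)) {
      if (w[r] == 1L) {
        if (label[r] == "hot") rt[r] <- rt[r] + 1
        label[r] <- "cold"
      } else if (w[r] == n_win) label[r] <- "hot"
    }
    for (r in seq_len(n)) {
      if (label[r] == "cold") n_cold[w[r]] <- n_cold[w[r]] + 1
      else if (label[r] == "hot") n_hot[w[r]] <- n_hot[w[r]] + 1
    }
  }
  list(round_trips = rt, n_cold = n_cold, n_hot = n_hot)
}

#' Write run artifacts as plain-text logs
#'
#' Emits \code{ladder_####.csv} per recorded ladder, \code{occupancy.csv}
#' (step, replica_id, window_index), \code{energies.csv} (step, window,
#' potential_energy), \code{exchange_rates.csv}, \code{histogram.csv} and a
#' \code{summary.json} echoing the configuration (minus the model closures)
#' and headline statistics.
#'
#' @param result a \code{run_result}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lh <- result$ladder_history
  for (i in seq_along(lh$times))
    write_ladder_csv(lh$ladders[[i]],
                     file.path(dir, sprintf("ladder_%05d.csv", lh$times[i])))
  occ <- result$occupancy
  n <- ncol(occ)
  occ_df <- data.frame(step = rep(seq_len(nrow(occ)), each = n),
                       replica_id = rep(seq_len(n), nrow(occ)),
                       window_index = as.vector(t(occ)))
  utils::write.csv(occ_df, file.path(dir, "occupancy.csv"),
                   row.names = FALSE, quote = FALSE)
  en <- result$energies
  en_df <- data.frame(step = rep(seq_len(nrow(en)), each = n),
                      window = rep(seq_len(n), nrow(en)),
                      potential_energy = as.vector(t(en)))
  utils::write.csv(en_df, file.path(dir, "energies.csv"),
                   row.names = FALSE, quote = FALSE)
  rates <- data.frame(pair_low_index = seq_len(n - 1L),
                      attempts = result$rep$attempts,
                      accepts = result$rep$accepts,
                      rate = exchange_rate_profile(result$rep))
  utils::write.csv(rates, file.path(dir, "exchange_rates.csv"),
                   row.names = FALSE, quote = FALSE)
  write_histogram_csv(result$hist, result$rep$ladder,
                      file.path(dir, "histogram.csv"))
  cfg <- result$config
  summ <- list(mode = cfg$mode, model = cfg$model$kind,
               model_params = as.list(cfg$model$params),
               t_min = cfg$t_min, t_max = cfg$t_max, n = cfg$n,
               seed = cfg$seed, n_rounds = cfg$n_rounds,
               steps_per_swap = cfg$steps_per_swap,
               dt = cfg$params$dt, gamma = cfg$params$gamma,
               lam = cfg$params$lam, t_l = cfg$params$t_l, kB = cfg$params$kB,
               round_trips = result$rep$round_trips,
               mean_round_trips = mean(result$rep$round_trips),
               final_temps = result$rep$ladder$temps)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Compare adaptive and static sampling over paired seeds
#'
#' Runs both configurations at each seed and reports per-mode round-trip and
#' exchange-rate statistics with means and standard errors. The two
#' configurations must be identical apart from the ladder mode (seeds are
#' supplied here).
#'
#' @param config_a,config_b \code{run_config}s differing only in \code{mode}.
#' @param seeds integer vector of seeds (paired across modes).
#' @return an object of class \code{mode_comparison}: per-seed mean round
#'   trips per mode, their means/SEs, per-pair exchange-rate profiles, and
#'   final ladders.
#' @export
compare_modes <- function(config_a, config_b, seeds) {
  fields <- setdiff(names(config_a), c("mode", "seed"))
  for (f in setdiff(fields, c("model", "params"))) {
    if (!identical(config_a[[f]], config_b[[f]]))
      stop("invalid comparison: configs differ in field '", f, "'")
  }
  if (!identical(config_a$model$kind, config_b$model$kind) ||
      !identical(config_a$model$params, config_b$model$params) ||
      !identical(unclass(config_a$params), unclass(config_b$params)))
    stop("invalid comparison: model or dynamics parameters differ")
  run_one <- function(cfg, seed) {
    cfg$seed <- as.integer(seed)
    run_simulation(cfg)
  }
  res_a <- lapply(seeds, run_one, cfg = config_a)
  res_b <- lapply(seeds, run_one, cfg = config_b)
  rt_a <- vapply(res_a, function(r) mean(r$rep$round_trips), numeric(1))
  rt_b <- vapply(res_b, function(r) mean(r$rep$round_trips), numeric(1))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  structure(list(
    mode_a = config_a$mode, mode_b = config_b$mode, seeds = seeds,
    round_trips_a = rt_a, round_trips_b = rt_b,
    mean_a = mean(rt_a), mean_b = mean(rt_b),
    se_a = se(rt_a), se_b = se(rt_b),
    rates_a = lapply(res_a, function(r) exchange_rate_profile(r$rep)),
    rates_b = lapply(res_b, function(r) exchange_rate_profile(r$rep)),
    final_ladder_a = lapply(res_a, function(r) r$rep$ladder),
    final_ladder_b = lapply(res_b, function(r) r$rep$ladder)),
    class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf("<mode_comparison> %s vs %s over %d seeds\n",
              x$mode_a, x$mode_b, length(x$seeds)))
  cat(sprintf("  mean round trips: %s = %.2f (SE %.2f), %s = %.2f (SE %.2f)\n",
              x$mode_a, x$mean_a, x$se_a, x$mode_b, x$mean_b, x$se_b))
  invisible(x)
}
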