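test_that("swap_probability closed form and symmetry", {
  expect_equal(swap_probability(1, 1, 5, -3), 1.0)
  expect_equal(swap_probability(2, 0.5, 4, 4), 1.0)
  expect_equal(swap_probability(1, 0.5, 2, 1), 1.0)            # e^{0.5} capped
  expect_equal(swap_probability(1, 0.5, 1, 2), exp(-0.5))
  expect_error(swap_probability(-1, 1, 0, 0))
  # relabeling symmetry on random inputs
  set.seed(5)
  for (k in 1:50) {
    ba <- runif(1, 0.1, 3); bb <- runif(1, 0.1, 3)
    ea <- rnorm(1, 0, 5); eb <- rnorm(1, 0, 5)
    expect_equal(swap_probability(ba, bb, ea, eb),
                 swap_probability(bb, ba, eb, ea), tolerance = 1e-14)
  }
})

test_that("attempt_swaps: parity pairing, bijection, acceptance bookkeeping", {
  l <- geometric_ladder(1, 2, 6)
  rep <- replica_set(l)
  set.seed(1)
  # identical energies: every attempted pair accepted with probability 1
  rep <- attempt_swaps(rep, rep(3.5, 6), "even")
  expect_equal(rep$attempts, c(1, 0, 1, 0, 1))
  expect_equal(rep$accepts, c(1, 0, 1, 0, 1))
  rep <- attempt_swaps(rep, rep(3.5, 6), "odd")
  expect_equal(rep$attempts, c(1, 1, 1, 1, 1))  # every pair attempted once
  expect_identical(sort(rep$window_of), 1:6)
  expect_identical(rep$window_of[rep$replica_in], 1:6)
})

test_that("empirical acceptance matches closed form (fixed energies)", {
  l <- temperature_ladder(c(1, 2))
  beta <- 1 / l$temps
  e <- c(1, 2)   # cold window lower energy -> acceptance < 1
  p_theory <- swap_probability(beta[1], beta[2], e[1], e[2])
  set.seed(42)
  n_try <- 2e4
  acc <- 0
  rep <- replica_set(l)
  for (k in seq_len(n_try)) {
    before <- rep$replica_in[1]
    rep <- attempt_swaps(rep, e, "even")
    if (rep$replica_in[1] != before) acc <- acc + 1
  }
  se <- sqrt(p_theory * (1 - p_theory) / n_try)
  expect_lt(abs(acc / n_try - p_theory), 3 * se)
})

test_that("walker labels and round trips follow forced trajectories", {
  l <- geometric_ladder(1, 2, 4)
  rep <- replica_set(l)
  rep <- update_walker_labels(rep)
  expect_equal(rep$label, c("cold", "unlabeled", "unlabeled", "hot"))
  expect_equal(rep$round_trips, rep(0, 4))
  # force replica 1 on the walk 1 -> 4 -> 1: exactly one round trip
  walk <- c(1, 2, 3, 4, 3, 2, 1)
  rep <- replica_set(l)
  for (w in walk) {
    perm <- seq_len(4)
    perm[c(1, w)] <- perm[c(w, 1)]   # put replica 1 in window w
    rep$window_of <- perm
    rep$replica_in <- order(perm)
    rep <- update_walker_labels(rep)
  }
  expect_equal(rep$round_trips[1], 1)
  # pinned at window 1 forever: cold, no trips
  rep2 <- replica_set(l)
  for (k in 1:10) rep2 <- update_walker_labels(rep2)
  expect_equal(rep2$label[1], "cold")
  expect_equal(rep2$round_trips[1], 0)
})

test_that("randomized forced walks: round trips equal replay recount", {
  set.seed(17)
  n <- 5
  l <- geometric_ladder(1, 2, n)
  for (trial in 1:10) {
    rep <- replica_set(l)
    n_rounds <- 400
    occ <- matrix(NA_integer_, n_rounds, n)
    for (t in seq_len(n_rounds)) {
      # random adjacent transposition = one accepted neighbor swap
      w <- sample(n - 1, 1)
      ra <- rep$replica_in[w]; rb <- rep$replica_in[w + 1]
      rep$replica_in[w] <- rb; rep$replica_in[w + 1] <- ra
      rep$window_of[ra] <- w + 1L; rep$window_of[rb] <- w
      rep <- update_walker_labels(rep)
      occ[t, ] <- rep$window_of
    }
    replay <- replay_occupancy(occ)
    expect_equal(replay$round_trips, rep$round_trips)
  }
})

test_that("record_visits counts labeled replicas only and matches replay", {
  l <- geometric_ladder(1, 2, 4)
  rep <- replica_set(l)
  h <- visit_histogram(numeric(4), numeric(4))
  # all unlabeled: nothing recorded
  expect_equal(record_visits(rep, h)$n_cold, numeric(4))
  rep$label <- c("cold", "unlabeled", "unlabeled", "hot")
  h <- record_visits(rep, h)
  expect_equal(h$n_cold, c(1, 0, 0, 0))
  expect_equal(h$n_hot, c(0, 0, 0, 1))
  # one cold replica in window 3
  rep2 <- replica_set(l)
  rep2$label <- c("unlabeled", "unlabeled", "cold", "unlabeled")
  h2 <- record_visits(rep2, visit_histogram(numeric(4), numeric(4)))
  expect_equal(h2$n_cold, c(0, 0, 1, 0))
})

test_that("exchange_rate_profile: fractions and undefined pairs", {
  fake <- list(attempts = c(100, 0, 10), accepts = c(30, 0, 10))
  r <- exchange_rate_profile(fake)
  expect_equal(r[1], 0.3)
  expect_true(is.na(r[2]))
  expect_equal(r[3], 1.0)
})

test_that("permutation stays a bijection over many randomized swap rounds", {
  set.seed(8)
  l <- geometric_ladder(1, 3, 8)
  rep <- replica_set(l)
  for (k in 1:2000) {
    e <- rnorm(8)
    rep <- attempt_swaps(rep, e, if (k %% 2) "even" else "odd")
  }
  expect_identical(sort(rep$window_of), 1:8)
  expect_identical(rep$window_of[rep$replica_in], 1:8)
  expect_true(all(rep$accepts <= rep$attempts))
})

test_that("two-temperature detailed balance: energy distributions match controls", {
  # harmonic replicas exchanging between T1 and T2: the x-samples collected
  # in each window must match a single-temperature control run (KS test)
  set.seed(123)
  m <- harmonic_model(1, 1)
  pr <- toy_params(dt = 0.2)
  l <- temperature_ladder(c(1, 2))
  cfg <- run_config(m, "static", 1, 2, 2, pr, steps_per_swap = 10,
                    n_rounds = 5000, seed = 99)
  res <- run_simulation(cfg)
  # occupancy symmetry: each replica spends about half its time cold
  frac_cold <- mean(res$occupancy[, 1] == 1)
  expect_gt(frac_cold, 0.45)
  expect_lt(frac_cold, 0.55)
  # window-1 energies vs exact Boltzmann potential-energy draws at T1
  e_cold <- res$energies[2001:5000, 1]
  ctrl <- 0.5 * 1 * rchisq(3000, df = 1)     # E = T/2 * chi^2_1 at T = 1
  ks <- suppressWarnings(stats::ks.test(e_cold, ctrl))
  expect_gt(ks$p.value, 0.01)
})
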