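test_that("geometric ladder: closed form, exact endpoints, constant ratio", {
  l <- ladder16()
  expect_identical(l$temps[1], 275)
  expect_identical(l$temps[16], 350)
  expect_equal(l$temps[2], 275 * (350 / 275)^(1 / 15), tolerance = 1e-14)
  ratios <- l$temps[-1] / l$temps[-16]
  expect_lt(max(abs(ratios - spacing_ratio(l))), 1e-12)
  # two-point ladder is just the endpoints
  expect_equal(geometric_ladder(300, 600, 2)$temps, c(300, 600))
  expect_equal(spacing_ratio(geometric_ladder(300, 600, 2)), 2)
})

test_that("geometric ladder rejects invalid arguments", {
  expect_error(geometric_ladder(350, 275, 16))
  expect_error(geometric_ladder(-1, 350, 16))
  expect_error(geometric_ladder(275, 350, 1))
  expect_error(temperature_ladder(c(300, 300, 350)))
})

test_that("spacing_ratio inverts construction for random ladders", {
  set.seed(11)
  for (k in 1:20) {
    t_min <- runif(1, 100, 400)
    r <- runif(1, 1.01, 1.4)
    n <- sample(3:20, 1)
    l <- temperature_ladder(t_min * r^(0:(n - 1)))
    expect_equal(spacing_ratio(l), r, tolerance = 1e-10)
  }
})

test_that("fraction_cold arithmetic and undefined windows", {
  h <- visit_histogram(c(3, 5, 0), c(1, 0, 0))
  f <- fraction_cold(h)
  expect_equal(f$f[1], 0.75)
  expect_equal(f$f[2], 1.0)
  expect_true(is.na(f$f[3]))
  # monotonicity: adding a cold visit never decreases f
  set.seed(4)
  for (k in 1:50) {
    nc <- rpois(1, 5); nh <- rpois(1, 5)
    if (nc + nh == 0) next
    f0 <- fraction_cold(visit_histogram(nc, nh))$f
    f1 <- fraction_cold(visit_histogram(nc + 1, nh))$f
    expect_gte(f1, f0)
  }
})

test_that("target_fraction is index-linear with correct boundaries", {
  expect_equal(target_fraction(0, 16), 1.0)
  expect_equal(target_fraction(15, 16), 0.0)
  expect_equal(target_fraction(5, 11), 0.5)
  expect_error(target_fraction(16, 16))
  expect_error(target_fraction(-1, 16))
})

test_that("interpolate_inverse: exact knots, hand interpolation, clamping", {
  p <- structure(list(f = c(1, 0.5, 0), temps = c(275, 310, 350)),
                 class = "fraction_profile")
  expect_equal(interpolate_inverse(p, 0.5), 310)
  p2 <- structure(list(f = c(1, 0), temps = c(275, 350)),
                  class = "fraction_profile")
  expect_equal(interpolate_inverse(p2, 0.25), 331.25)
  expect_equal(interpolate_inverse(p2, 1), 275)
  expect_equal(interpolate_inverse(p2, 0), 350)
  expect_error(interpolate_inverse(
    structure(list(f = c(1, NA), temps = c(275, 350)),
              class = "fraction_profile"), 0.5), "insufficient")
})

test_that("interpolate_inverse agrees with dense-grid oracle, incl. non-monotone", {
  # the spec's non-monotone example
  p <- structure(list(f = c(1, 0.2, 0.4, 0), temps = c(275, 300, 325, 350)),
                 class = "fraction_profile")
  got <- interpolate_inverse(p, 0.3)
  oracle <- grid_invert(p$temps, p$f, 0.3)
  expect_lt(abs(got - oracle), diff(range(p$temps)) / 1e4 * 2)
  # randomized monotone profiles
  set.seed(21)
  for (k in 1:25) {
    n <- sample(4:12, 1)
    temps <- sort(runif(n, 275, 350))
    f <- sort(runif(n), decreasing = TRUE)
    tgt <- runif(1, min(f), max(f))
    got <- interpolate_inverse(
      structure(list(f = f, temps = temps), class = "fraction_profile"), tgt)
    oracle <- grid_invert(temps, f, tgt)
    expect_lt(abs(got - oracle), diff(range(temps)) / 1e4 * 2)
  }
})

test_that("enforce_spacing_constraint: projection properties", {
  l <- ladder16()
  r <- spacing_ratio(l)
  # a geometric ladder passes through unchanged
  expect_equal(enforce_spacing_constraint(l$temps, r, 275, 350), l$temps)
  # interior clustered at t_max: afterwards every ratio <= r^2, endpoints exact
  temps <- c(275, rep(350, 15))
  out <- enforce_spacing_constraint(temps, r, 275, 350)
  expect_identical(out[1], 275)
  expect_identical(out[16], 350)
  expect_lte(max(out[-1] / out[-16]), r^2 * (1 + 1e-12))
  # one oversized gap of ratio r^3
  temps <- l$temps
  temps[8:16] <- temps[8:16] * r^2   # creates a gap of r^3 at pair 7-8
  temps <- pmin(temps, 350)
  out <- enforce_spacing_constraint(sort(temps), r, 275, 350)
  expect_lt(max(out[-1] / out[-16]), r^2 + 1e-12)
  # randomized inputs always satisfy the constraint and keep endpoints
  set.seed(31)
  for (k in 1:200) {
    n <- sample(3:16, 1)
    tmin <- runif(1, 100, 300); tmax <- tmin * runif(1, 1.2, 3)
    rr <- (tmax / tmin)^(1 / (n - 1))
    temps <- sort(c(tmin, runif(n - 2, tmin, tmax), tmax))
    out <- enforce_spacing_constraint(temps, rr, tmin, tmax)
    expect_identical(out[1], tmin)
    expect_identical(out[n], tmax)
    expect_lte(max(out[-1] / out[-n]), rr^2 * (1 + 1e-12))
    expect_false(is.unsorted(out))
  }
  # infeasible span
  expect_error(enforce_spacing_constraint(c(1, 100), 1.2, 1, 100), "infeasible")
})

test_that("adapt_temperatures: idempotent on index-linear profiles", {
  l <- ladder16()
  # counts whose fraction-cold equals the index-linear target exactly
  n <- l$n
  tgt <- target_fraction(0:(n - 1), n)
  n_cold <- as.integer(round(15000 * tgt))   # exact integers: 15000/15 divides
  n_hot <- 15000L - n_cold
  new <- adapt_temperatures(l, visit_histogram(n_cold, n_hot))
  expect_lt(max(abs(new$temps - l$temps)), 1e-9)
})

test_that("adapt_temperatures: step profile concentrates but never collapses", {
  l <- geometric_ladder(275, 350, 16)
  tc <- 310
  f_step <- as.numeric(l$temps < tc)
  n_cold <- round(100 * f_step); n_hot <- 100 - n_cold
  new <- adapt_temperatures(l, visit_histogram(n_cold, n_hot))
  r <- spacing_ratio(l)
  expect_identical(new$temps[1], 275)
  expect_identical(new$temps[16], 350)
  expect_lte(max(new$temps[-1] / new$temps[-16]), r^2 * (1 + 1e-12))
  expect_true(all(diff(new$temps) > 0))
  # interior mass moves toward the step: median interior temp near tc
  expect_lt(abs(stats::median(new$temps[2:15]) - tc), 15)
})

test_that("adapt_temperatures matches dense-grid equal-f inversion for linear-in-T profile", {
  l <- geometric_ladder(275, 350, 8)
  # f linear in TEMPERATURE: f(T) = (t_max - T)/(t_max - t_min)
  f <- (350 - l$temps) / 75
  n_cold <- round(1e6 * f); n_hot <- 1e6 - n_cold
  new <- adapt_temperatures(l, visit_histogram(n_cold, n_hot))
  # equal-f-spacing solution: targets 1 - i/7 inverted through the linear f
  expected <- 350 - target_fraction(0:7, 8) * 75
  expected[1] <- 275; expected[8] <- 350
  expect_equal(new$temps, expected, tolerance = 1e-5)
})

test_that("adapt_temperatures requires visited endpoint windows", {
  l <- geometric_ladder(275, 350, 4)
  expect_error(adapt_temperatures(l, visit_histogram(c(0, 1, 1, 1), c(0, 1, 1, 1))),
               "insufficient")
})

test_that("ladder and histogram CSV round-trips", {
  l <- ladder16()
  f <- tempfile(fileext = ".csv")
  write_ladder_csv(l, f)
  expect_equal(read_ladder_csv(f)$temps, l$temps, tolerance = 1e-12)
  h <- visit_histogram(1:16, 16:1)
  f2 <- tempfile(fileext = ".csv")
  write_histogram_csv(h, l, f2)
  back <- read_histogram_csv(f2)
  expect_equal(back$hist$n_cold, as.numeric(1:16))
  expect_equal(back$ladder$temps, l$temps, tolerance = 1e-12)
  unlink(c(f, f2))
})

test_that("interpolate_inverse handles a fully flat regressed profile", {
  # an increasing empirical profile isotonically regresses to a constant
  p <- structure(list(f = c(0.2, 0.4, 0.6), temps = c(275, 310, 350)),
                 class = "fraction_profile")
  expect_equal(interpolate_inverse(p, 0.9), 275)   # colder than the constant
  expect_equal(interpolate_inverse(p, 0.1), 350)   # hotter than the constant
  expect_equal(interpolate_inverse(p, 0.4), 312.5) # the constant itself
})
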