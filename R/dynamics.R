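#' Langevin and self-guided Langevin (SGLD) integration
#'
#' SGLD augments Langevin dynamics with a guiding force proportional to a
#' local time-average of the momentum, scaled by a guiding factor lambda:
#' \deqn{dp/dt = f(x) - \gamma p + R(t) + \lambda \gamma \langle p \rangle_L}
#' where the memory term \eqn{\langle p \rangle_L} is the moving average of
#' the momentum over an averaging time t_L (window L = t_L/dt steps),
#' maintained recursively. With lambda = 0 the integrator reduces exactly to
#' plain Langevin dynamics. Discretization is a BAOAB splitting: the guiding
#' force is added to the systematic force in the B sub-steps, and the O
#' sub-step applies the exact Ornstein-Uhlenbeck update, which realizes the
#' fluctuation-dissipation balance at the window temperature.
#'
#' @name dynamics
NULL

#' Dynamics parameters
#'
#' @param dt integration time step (ps in physical mode, reduced otherwise);
#'   positive.
#' @param gamma friction constant (1/time), >= 0.
#' @param lam guiding factor lambda (dimensionless); 0 gives plain Langevin.
#' @param t_l momentum averaging time, >= dt.
#' @param masses per-particle masses (recycled over dofs), positive.
#' @param kB Boltzmann constant (1 reduced, \code{KB_KCAL} physical).
#' @return an object of class \code{dynamics_params}.
#' @export
dynamics_params <- function(dt, gamma = 1, lam = 1, t_l = 50 * dt,
                            masses = 1, kB = 1) {
  if (dt <= 0) stop("dt must be positive")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (t_l < dt) stop("t_l must be at least dt")
  if (any(masses <= 0)) stop("masses must be positive")
  structure(list(dt = dt, gamma = gamma, lam = lam, t_l = t_l,
                 masses = masses, kB = kB),
            class = "dynamics_params")
}

#' Physical-unit SGLD defaults
#'
#' dt = 2 fs, gamma = 1 / ps, lambda = 1, t_L = 1 ps, kB in kcal/(mol K) —
#' the parameter set used for protein refinement runs.
#' @param masses per-particle masses (amu).
#' @return a \code{dynamics_params}.
#' @export
sgld_defaults_physical <- function(masses = 12) {
  dynamics_params(dt = 0.002, gamma = 1, lam = 1, t_l = 1,
                  masses = masses, kB = KB_KCAL)
}

#' Replica dynamical state
#'
#' @param x coordinates; \code{p} momenta; \code{p_avg} momentum memory.
#' @param p,p_avg optional, default zero.
#' @return an object of class \code{replica_dyn_state}.
#' @export
replica_dyn_state <- function(x, p = NULL, p_avg = NULL) {
  x <- as.numeric(x)
  if (is.null(p)) p <- numeric(length(x))
  if (is.null(p_avg)) p_avg <- numeric(length(x))
  if (length(p) != length(x) || length(p_avg) != length(x))
    stop("x, p, p_avg must have equal length")
  if (any(!is.finite(c(x, p, p_avg)))) stop("state must be finite")
  structure(list(x = x, p = p, p_avg = p_avg), class = "replica_dyn_state")
}

#' Recursive moving average of the momentum
#'
#' \code{p_avg <- (1 - dt/t_l) p_avg + (dt/t_l) p}: the exponential local
#' average over a window of L = t_l/dt steps.
#'
#' @param p_avg current memory; \code{p} current momenta.
#' @param p momenta.
#' @param dt time step; \code{t_l} averaging time, >= dt.
#' @param t_l averaging time.
#' @return updated memory.
#' @export
update_momentum_average <- function(p_avg, p, dt, t_l) {
  if (t_l < dt) stop("t_l must be at least dt")
  w <- dt / t_l
  (1 - w) * p_avg + w * p
}

#' Guiding force
#'
#' @param p_avg momentum memory.
#' @param gamma friction constant.
#' @param lam guiding factor.
#' @return \code{lam * gamma * p_avg}.
#' @export
guiding_force <- function(p_avg, gamma, lam) lam * gamma * p_avg

.dof_masses <- function(params, d) rep_len(params$masses, d)

.check_finite_force <- function(f) {
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1L]
    stop(sprintf("numerical blowup: non-finite force at coordinate %d", bad))
  }
  f
}

#' One SGLD step (BAOAB splitting), pure-R reference path
#'
#' Draws exactly \code{length(x)} standard normals from the R RNG per step
#' (also when gamma = 0, to keep noise streams alignable across integrators).
#'
#' @param state a \code{replica_dyn_state}.
#' @param model an \code{energy_model}.
#' @param temp window temperature, positive.
#' @param params a \code{dynamics_params}.
#' @return the updated \code{replica_dyn_state}.
#' @export
sgld_step <- function(state, model, temp, params) {
  if (temp <= 0) stop("temperature must be positive")
  d <- length(state$x)
  m <- .dof_masses(params, d)
  dt <- params$dt
  x <- state$x; p <- state$p; pa <- state$p_avg
  f <- .check_finite_force(-model$gradient(x)) +
    guiding_force(pa, params$gamma, params$lam)
  p <- p + 0.5 * dt * f
  x <- x + 0.5 * dt * p / m
  c1 <- exp(-params$gamma * dt)
  c2 <- sqrt((1 - c1 * c1) * m * params$kB * temp)
  p <- c1 * p + c2 * stats::rnorm(d)
  x <- x + 0.5 * dt * p / m
  f <- .check_finite_force(-model$gradient(x)) +
    guiding_force(pa, params$gamma, params$lam)
  p <- p + 0.5 * dt * f
  pa <- update_momentum_average(pa, p, dt, params$t_l)
  replica_dyn_state(x, p, pa)
}

#' One plain Langevin step (BAOAB), independent of the SGLD path
#'
#' Kept as a separate implementation (no momentum memory) so the lambda = 0
#' reduction of \code{\link{sgld_step}} can be verified against it on a
#' shared noise stream.
#'
#' @inheritParams sgld_step
#' @return the updated \code{replica_dyn_state} (\code{p_avg} untouched).
#' @export
langevin_step <- function(state, model, temp, params) {
  if (temp <= 0) stop("temperature must be positive")
  d <- length(state$x)
  m <- .dof_masses(params, d)
  dt <- params$dt
  x <- state$x; p <- state$p
  p <- p + 0.5 * dt * .check_finite_force(-model$gradient(x))
  x <- x + 0.5 * dt * p / m
  c1 <- exp(-params$gamma * dt)
  c2 <- sqrt((1 - c1 * c1) * m * params$kB * temp)
  p <- c1 * p + c2 * stats::rnorm(d)
  x <- x + 0.5 * dt * p / m
  p <- p + 0.5 * dt * .check_finite_force(-model$gradient(x))
  replica_dyn_state(x, p, state$p_avg)
}

.compiled_model_id <- function(model) {
  switch(model$kind, harmonic = 1L, double_well = 2L, 0L)
}

#' Integrate a segment between swap attempts
#'
#' Applies \code{n_steps} SGLD steps and returns the final state together
#' with the instantaneous potential energy (used by the Metropolis swap
#' test) and the segment-mean potential energy. Models recognized by the
#' compiled integrator (harmonic, double well) use a C++ fast path drawing
#' from the same R RNG stream in the same order as the reference path;
#' \code{use_compiled = FALSE} forces the pure-R path.
#'
#' @inheritParams sgld_step
#' @param n_steps number of steps, >= 1 (500 steps at dt = 2 fs spans the
#'   1 ps exchange cadence of the physical parameter set).
#' @param use_compiled logical; default consults
#'   \code{getOption("adaptrex.compiled", TRUE)}.
#' @return list with \code{state}, \code{e_pot} (final), \code{e_mean}.
#' @export
run_segment <- function(state, model, temp, params, n_steps,
                        use_compiled = getOption("adaptrex.compiled", TRUE)) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("need n_steps >= 1")
  d <- length(state$x)
  mid <- .compiled_model_id(model)
  if (use_compiled && mid > 0L) {
    out <- cpp_run_segment(state$x, state$p, state$p_avg,
                           .dof_masses(params, d), params$dt, params$gamma,
                           params$lam, params$t_l, params$kB * temp,
                           n_steps, mid, unname(model$params))
    return(list(state = replica_dyn_state(out$x, out$p, out$p_avg),
                e_pot = out$e_pot, e_mean = out$e_mean))
  }
  esum <- 0
  for (s in seq_len(n_steps)) {
    state <- sgld_step(state, model, temp, params)
    esum <- esum + model$energy(state$x)
  }
  list(state = state, e_pot = model$energy(state$x), e_mean = esum / n_steps)
}
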