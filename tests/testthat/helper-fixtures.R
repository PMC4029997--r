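# shared fixtures built in code

ladder16 <- function() geometric_ladder(275, 350, 16)

# 3 collinear beads 5 A apart: native contacts {(1,2),(2,3)} at cutoff 6.5
beads3 <- function() {
  bead_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
}

rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# brute-force inversion oracle: dense grid over the profile's range; flat
# stretches at the target resolve to the midpoint of the level set, matching
# the implementation's tie rule
grid_invert <- function(temps, f, target, n_grid = 1e4) {
  fhat <- -stats::isoreg(temps, -f)$yf
  tg <- seq(min(temps), max(temps), length.out = n_grid)
  fg <- stats::approx(temps, fhat, xout = tg)$y
  d <- abs(fg - target)
  hit <- which(d <= min(d) + 1e-12)
  mean(range(tg[hit]))
}

# reduced-unit dynamics defaults used across dynamics tests
toy_params <- function(dt = 0.1, gamma = 1, lam = 1, t_l = 50 * dt)
  dynamics_params(dt = dt, gamma = gamma, lam = lam, t_l = t_l)
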