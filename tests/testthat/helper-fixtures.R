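# Boltzmann constant (J/K), duplicated here so oracle arithmetic in tests
# stays independent of the package internals it checks.
kB <- 1.380649e-23

# study conditions: Maxwell media for phosphorylated (CA) and
# unphosphorylated (KD) condensates
caModel <- function() mediumModel("maxwell", eta0 = 31.8, tau = 4.6)
kdModel <- function() mediumModel("maxwell", eta0 = 3.8, tau = 1.03)

# Stokes-Einstein diffusivity, um^2/s -- independent closed form
seDiffusivity <- function(eta, a = 50e-9, Tk = 303.15) {
  kB * Tk / (6 * pi * eta * a) * 1e12
}

# closed-form Maxwell moduli at omega (independent of analyticModuli)
maxwellGp <- function(G0, tau, om) G0 * (om * tau)^2 / (1 + (om * tau)^2)
maxwellGpp <- function(G0, tau, om) G0 * om * tau / (1 + (om * tau)^2)

# a stationary single-bead TrajectorySet at (x, y) um for rendering tests
staticBead <- function(x = 0, y = 0, nFrames = 1) {
  traj <- simulateTrajectories(mediumModel("newtonian", eta = 1),
                               nBeads = 1, nFrames = 2, dt = 0.015,
                               seed = 1)
  d <- trajectories(traj)[rep(1, nFrames), ]
  d$frame <- seq_len(nFrames) - 1L
  d$t_s <- d$frame * 0.015
  d$x_um <- x; d$y_um <- y
  rownames(d) <- NULL
  traj@data <- d
  traj
}

# simulated beads arranged on a grid (guaranteed separation) for
# render-and-track round trips
gridTrajectories <- function(model, nBeads = 16, nFrames = 300,
                             spacing = 3, seed = 5) {
  traj <- simulateTrajectories(model, nBeads = nBeads, nFrames = nFrames,
                               dt = 0.015, seed = seed)
  side <- ceiling(sqrt(nBeads))
  off <- (seq_len(side) - (side + 1) / 2) * spacing
  gx <- rep(off, side)[seq_len(nBeads)]
  gy <- rep(off, each = side)[seq_len(nBeads)]
  d <- trajectories(traj)
  d$x_um <- d$x_um + gx[d$trajectory_id]
  d$y_um <- d$y_um + gy[d$trajectory_id]
  traj@data <- d
  traj
}
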