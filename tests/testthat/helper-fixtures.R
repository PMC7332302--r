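# Shared in-code fixtures for the suite.

# n straight-line trajectories all moving at `angle` (radians from +x),
# `speed` um/h, observed at frames 0..n_steps with dt hours per step.
straight_tracks <- function(n, angle = 0, speed = 10, n_steps = 36,
                            dt = 1 / 6, viewfield = "vf1",
                            condition = "fix") {
  rows <- lapply(seq_len(n), function(i) {
    t <- (0:n_steps) * dt
    data.frame(cell_id = sprintf("c%03d", i), frame = 0:n_steps,
               time_h = t,
               x = speed * t * cos(angle) + i,     # offset start per cell
               y = speed * t * sin(angle) - i,
               viewfield = viewfield, condition = condition,
               stringsAsFactors = FALSE)
  })
  etaxis::tracks(do.call(rbind, rows), frame_interval = dt * 60)
}

# two-point tracks with explicit per-cell displacement vectors
displacement_tracks <- function(dxy, elapsed_h = 6) {
  rows <- lapply(seq_len(nrow(dxy)), function(i) {
    data.frame(cell_id = sprintf("c%03d", i), frame = c(0, 1),
               time_h = c(0, elapsed_h),
               x = c(0, dxy[i, 1]), y = c(0, dxy[i, 2]),
               viewfield = "vf1", condition = "fix",
               stringsAsFactors = FALSE)
  })
  etaxis::tracks(do.call(rbind, rows), frame_interval = elapsed_h * 60)
}

# mean resultant length of a von Mises distribution by numerical
# quadrature: A(kappa) = I1(kappa)/I0(kappa), computed without Bessel
# functions (independent oracle for the simulator).
vm_mrl_quadrature <- function(kappa) {
  num <- stats::integrate(function(t) cos(t) * exp(kappa * cos(t)),
                          -pi, pi, rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) exp(kappa * cos(t)),
                          -pi, pi, rel.tol = 1e-10)$value
  num / den
}
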