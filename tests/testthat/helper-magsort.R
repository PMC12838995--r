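# Shared fixtures and independent finite-difference oracles.

dev0 <- default_device()
flow0 <- build_flow(dev0)
mat0 <- dev0$materials
mu0 <- 4e-7 * pi

# H = B/mu0 at a point, via the package field
H_at <- function(dev, x, z) {
  f <- total_field(x, z, dev)
  c(f$Bx, f$Bz) / mu0
}

# central-difference Jacobian of H: independent of the analytic derivatives
fd_jacobian_H <- function(dev, x, z, hs = 2e-8) {
  cbind((H_at(dev, x + hs, z) - H_at(dev, x - hs, z)) / (2 * hs),
        (H_at(dev, x, z + hs) - H_at(dev, x, z - hs)) / (2 * hs))
}

# a quiescent flow object (no net flow) for kinematic edge cases
still_flow <- function(h = dev0$geometry$channel_height,
                       viscosity = mat0$fluid_viscosity) {
  structure(list(Q_total = 0, mean_velocity = 0,
                 profile = function(z) rep(0, length(z)),
                 sample_band = c(0, h), channel_height = h,
                 viscosity = viscosity),
            class = "magsort_flow")
}
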