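test_that("a single step reproduces the closed-form semi-implicit update", {
  cj <- conjugate(15e-6, 0, mat0)
  st <- list(position = c(5e-3, 50e-6), velocity = c(1e-3, -2e-4), time = 0)
  Ffab <- c(3e-11, -8e-11) # fabricated constant force
  dt <- 1e-5
  out <- euler_step(st, cj, dev0, flow0, dt = dt, force = Ffab)
  # closed form: v' = (m v + dt (F + gamma u_f)) / (m + dt gamma)
  m <- cj$mass
  gam <- 6 * pi * mat0$fluid_viscosity * cj$radius
  uf <- flow0$profile(50e-6)
  vx <- (m * 1e-3 + dt * (Ffab[1] + gam * uf)) / (m + dt * gam)
  vz <- (m * -2e-4 + dt * Ffab[2]) / (m + dt * gam)
  expect_equal(out$velocity, c(vx, vz), tolerance = 1e-14)
  expect_equal(out$position, st$position + dt * c(vx, vz),
               tolerance = 1e-14)
  # forward scheme: v' = v + dt/m (F + gamma (u_f - v))
  outf <- euler_step(st, cj, dev0, flow0, dt = dt, scheme = "forward",
                     force = Ffab)
  expect_equal(outf$velocity[1],
               1e-3 + dt / m * (Ffab[1] + gam * (uf - 1e-3)),
               tolerance = 1e-14)
})

test_that("compiled and reference integrators take identical steps", {
  # one step of the compiled engine vs the independently written R step,
  # with the real magnetophoretic force
  cj <- conjugate(15e-6, 5, mat0)
  start <- c(8.2e-3, 30e-6)
  tr <- simulate_cell(cj, start, dev0, flow0, max_time = 1e-5,
                      window = Inf, record_every = 1L)
  st <- list(position = start, velocity = c(0, 0), time = 0)
  ref <- euler_step(st, cj, dev0, flow0, dt = 1e-5)
  expect_equal(tr$final$position, ref$position, tolerance = 1e-12)
  expect_equal(tr$final$velocity, ref$velocity, tolerance = 1e-12)
})

test_that("with zero force and zero flow the state only advances in time", {
  cj <- conjugate(15e-6, 0, mat0)
  st <- list(position = c(5e-3, 40e-6), velocity = c(0, 0), time = 0)
  out <- euler_step(st, cj, dev0, still_flow(), force = c(0, 0))
  expect_equal(out$position, st$position)
  expect_equal(out$velocity, c(0, 0))
  expect_gt(out$time, 0)
})

test_that("an unlabelled cell relaxes to the fluid velocity within ~5 tau", {
  cj <- conjugate(15e-6, 0, mat0)
  gam <- 6 * pi * mat0$fluid_viscosity * cj$radius
  tau <- cj$mass / gam
  expect_equal(tau, 1.3e-5, tolerance = 0.02)
  dt <- 1e-6
  n <- ceiling(5 * tau / dt)
  st <- list(position = c(0, 50e-6), velocity = c(0, 0), time = 0)
  for (k in seq_len(n)) st <- euler_step(st, cj, dev0, flow0, dt = dt)
  expect_equal(st$velocity[1], flow0$profile(st$position[2]),
               tolerance = 0.01)
  expect_equal(st$velocity[2], 0)
})

test_that("unlabelled cells pass through; trajectories are bit-deterministic", {
  cj0 <- conjugate(15e-6, 0, mat0)
  tr0 <- simulate_cell(cj0, c(0, 50e-6), dev0, flow0)
  expect_identical(tr0$outcome, "passed_through")
  expect_equal(tail(tr0$path$z, 1), 50e-6) # no vertical force, no settling
  cj <- conjugate(15e-6, 8, mat0)
  a <- simulate_cell(cj, c(0, 50e-6), dev0, flow0)
  b <- simulate_cell(cj, c(0, 50e-6), dev0, flow0)
  expect_identical(a$path, b$path)
  expect_identical(a$capture_x, b$capture_x)
})

test_that("captured cells decelerate through growing velocity oscillations", {
  cj <- conjugate(15e-6, 5, mat0)
  tr <- simulate_cell(cj, c(0, 50e-6), dev0, flow0)
  expect_identical(tr$outcome, "captured")
  p <- tr$path
  # final velocity below the capture threshold; at least one interior
  # max/min pair in vx
  expect_lt(abs(tail(p$vx, 1)), 1e-7)
  expect_gt(sum(diff(sign(diff(p$vx))) < 0), 1)
  expect_gt(sum(diff(sign(diff(p$vx))) > 0), 1)
  # kinetic energy at capture is a vanishing fraction of its peak
  ke <- p$vx^2 + p$vz^2
  expect_lt(tail(ke, 1) / max(ke), 1e-3)
  # capture means sustained floor contact
  expect_equal(tail(p$z, 1), cj$radius)
})

test_that("start positions outside the fluid domain are rejected", {
  cj <- conjugate(15e-6, 2, mat0)
  expect_error(simulate_cell(cj, c(0, 2e-6), dev0, flow0), "start height")
  expect_error(simulate_cell(cj, c(0, 99e-6), dev0, flow0), "start height")
})

test_that("capture classification maps strips to the H/M/L/N regions", {
  expect_identical(as.character(classify(5)), "H")
  expect_identical(as.character(classify(9)), "H")
  expect_identical(as.character(classify(10)), "M")
  expect_identical(as.character(classify(14)), "M")
  expect_identical(as.character(classify(19)), "L")
  expect_identical(as.character(classify(23)), "L")
  expect_identical(as.character(classify(NA)), "N")
  expect_identical(as.character(classify("passed_through")), "N")
  expect_error(classify(0), "strip index")
  expect_error(classify(28), "strip index")
})

test_that("static equilibria exist only for labelled cells and are stable", {
  # n_b = 0: drag is never balanced
  eq0 <- equilibrium_profile(conjugate(15e-6, 0, mat0), dev0, flow0,
                             xlim = c(1e-3, 5e-3))
  expect_length(eq0$stable_zeros, 0)
  expect_true(all(eq0$force > 0))
  cj <- conjugate(15e-6, 6, mat0)
  eq <- equilibrium_profile(cj, dev0, flow0)
  expect_gt(length(eq$stable_zeros), 0)
  # stable zeros have negative force slope
  for (x0 in eq$stable_zeros) {
    f <- magsort:::.equilibrium_force(x0 + c(-2e-6, 2e-6), cj, dev0, flow0)
    expect_gt(f[1], 0)
    expect_lt(f[2], 0)
  }
})

test_that("dynamic capture positions track the static equilibria", {
  for (nb in c(2, 6)) {
    cj <- conjugate(15e-6, nb, mat0)
    tr <- simulate_cell(cj, c(0, 50e-6), dev0, flow0)
    eq <- equilibrium_profile(cj, dev0, flow0,
                              xlim = tr$capture_x + c(-1.5e-3, 1.5e-3))
    expect_identical(tr$outcome, "captured")
    expect_gt(length(eq$stable_zeros), 0)
    # within one strip period, with a small downstream shift at most
    expect_lt(min(abs(eq$stable_zeros - tr$capture_x)),
              dev0$geometry$strip_period)
  }
})

test_that("the integrator converges under strip-window widening", {
  cj <- conjugate(15e-6, 5, mat0)
  a <- simulate_cell(cj, c(0, 50e-6), dev0, flow0, window = 4e-3)
  b <- simulate_cell(cj, c(0, 50e-6), dev0, flow0, window = Inf)
  expect_lt(abs(a$capture_x - b$capture_x) / b$capture_x, 5e-3)
})
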