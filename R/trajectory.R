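# Single-cell motion through the coupled field and flow: semi-implicit
# (drag-implicit) Euler integration with floor contact, Coulomb friction and
# capture detection; static equilibrium profiles along the array.
#
# The magnetophoretic force is evaluated at the bead-cluster position -- the
# cell's bottom pole plus one bead radius (beads localize on the face of the
# cell nearest the gradient source), so at floor contact the force sample
# height is independent of cell size.

# parameters handed to the compiled integrator
.traj_pars <- function(conj, device, flow, dt = NULL, max_time = NULL,
                       scheme = c("semi_implicit", "forward"),
                       window = 4e-3, record_every = 100L) {
  scheme <- match.arg(scheme)
  o <- device$operating
  list(
    radius = conj$radius,
    n_b = conj$n_b,
    force_coef = conj$n_b * .mu0 * conj$bead_volume *
      3 * (conj$chi_b - conj$chi_f) / ((conj$chi_b - conj$chi_f) + 3),
    mass = conj$mass,
    gamma = 6 * pi * flow$viscosity * conj$radius,
    u_mean = flow$mean_velocity,
    channel_height = flow$channel_height,
    friction_mu = o$friction_mu,
    dt = if (is.null(dt)) o$dt else dt,
    max_time = if (is.null(max_time)) o$max_time else max_time,
    z_force_offset = -conj$radius + device$materials$bead_diameter / 2,
    window = window,
    g_force = 0, # gravity/buoyancy off by default
    forward_euler = scheme == "forward",
    static_eps = 1e-7,
    capture_eps = 1e-7,
    capture_steps = 1000L,
    record_every = as.integer(record_every)
  )
}

#' One integrator step
#'
#' Reference (R) implementation of a single update of the trajectory state:
#' Newtonian dynamics `m dv/dt = F_drag + F_mag + F_friction + F_reaction`
#' with the drag term treated implicitly (`scheme = "semi_implicit"`,
#' unconditionally stable) or fully explicitly (`"forward"`), then an
#' explicit position update with floor/ceiling clamping. The compiled
#' integrator used by [simulate_cell()] performs the identical update; this
#' function exists as its its independently-written oracle and for
#' inspecting single steps.
#'
#' @param state list with `position` (c(x, z), m), `velocity`
#'   (c(vx, vz), m/s), `time` (s).
#' @param conj a [conjugate()].
#' @param device a `magsort_device`.
#' @param flow a [build_flow()] object.
#' @param dt time step, s.
#' @param scheme integration scheme.
#' @param force optional fixed external force c(Fx, Fz), N, replacing the
#'   magnetophoretic force (for closed-form checks).
#' @return the updated state (with `in_contact`).
#' @export
euler_step <- function(state, conj, device, flow, dt = device$operating$dt,
                       scheme = c("semi_implicit", "forward"), force = NULL) {
  scheme <- match.arg(scheme)
  p <- .traj_pars(conj, device, flow, dt = dt, scheme = scheme)
  x <- state$position[1]; z <- state$position[2]
  vx <- state$velocity[1]; vz <- state$velocity[2]
  R <- p$radius; h <- p$channel_height
  if (is.null(force)) {
    if (conj$n_b > 0) {
      fs <- total_field(x, z + p$z_force_offset, device)
      force <- as.numeric(magnetophoretic_force(conj, fs))
    } else force <- c(0, 0)
  }
  Fx <- force[1]; Fz <- force[2] + p$g_force
  uf <- flow$profile(z)
  m <- p$mass; gam <- p$gamma
  contact <- z <= R + 1e-15
  upd <- function(v, Fother, ufl) {
    if (scheme == "forward") v + dt / m * (Fother + gam * (ufl - v))
    else (m * v + dt * (Fother + gam * ufl)) / (m + dt * gam)
  }
  if (contact) {
    N <- max(0, -Fz)
    Fapp <- Fx + gam * (uf - vx)
    if (abs(vx) <= p$static_eps && abs(Fapp) <= p$friction_mu * N) {
      vx_new <- 0
    } else {
      dir <- if (abs(vx) > p$static_eps) sign(vx) else sign(Fapp)
      vx_new <- upd(vx, Fx - dir * p$friction_mu * N, uf)
      if (vx_new * dir < 0) vx_new <- 0
    }
    vz_new <- upd(vz, Fz, 0)
  } else {
    vx_new <- upd(vx, Fx, uf)
    vz_new <- upd(vz, Fz, 0)
  }
  x <- x + dt * vx_new
  z <- z + dt * vz_new
  if (z <= R) {
    z <- R
    if (vz_new < 0) vz_new <- 0
    contact <- TRUE
  } else contact <- FALSE
  if (z >= h - R) {
    z <- h - R
    if (vz_new > 0) vz_new <- 0
  }
  list(position = c(x, z), velocity = c(vx_new, vz_new),
       in_contact = contact, time = state$time + dt)
}

#' Simulate a single cell
#'
#' Integrates the conjugate from `start` until it is captured (floor
#' contact with |v| below 1e-7 m/s for 1000 consecutive steps), exits the
#' sorting zone, or `max_time` elapses (flagged `indeterminate`).
#' Deterministic for fixed inputs.
#'
#' @param conj a [conjugate()].
#' @param start `c(x0, z0)` start position, m (normally inside the sample
#'   band; the cell center must lie in `[radius, channel_height - radius]`).
#' @param device a `magsort_device`.
#' @param flow optional prebuilt [build_flow()].
#' @param dt,max_time integration step and cap, s (device defaults).
#' @param scheme `"semi_implicit"` (default) or the textbook `"forward"`
#'   Euler scheme.
#' @param window strip-superposition truncation radius for the integrator,
#'   m (`Inf` for the full sum); far strips contribute <0.3% of the local
#'   field.
#' @param record_every path sampling stride, steps.
#' @return object of class `magsort_trajectory`: list with `outcome`
#'   (`"captured"`, `"passed_through"` or `"indeterminate"`),
#'   `capture_strip` (1..strip_count or NA), `capture_x` (m or NA), `path`
#'   (data.frame t, x, z, vx, vz, contact), `final` state, and the inputs.
#' @export
simulate_cell <- function(conj, start, device, flow = build_flow(device),
                          dt = NULL, max_time = NULL,
                          scheme = c("semi_implicit", "forward"),
                          window = 4e-3, record_every = 100L) {
  g <- device$geometry
  R <- conj$radius
  if (start[2] < R - 1e-12 || start[2] > g$channel_height - R + 1e-12)
    stop("start height outside the fluid domain for this cell size",
         call. = FALSE)
  p <- .traj_pars(conj, device, flow, dt = dt, max_time = max_time,
                  scheme = scheme, window = window,
                  record_every = record_every)
  strips <- strip_sources(device)
  res <- cpp_simulate(start[1], start[2], .strip_matrix(strips),
                      device$operating$B_at_last_strip,
                      background_exponent(device), g$magnet_face_x,
                      g$sorting_length, p)
  outcome <- c("captured", "passed_through", "indeterminate")[res$outcome + 1]
  capture_x <- if (outcome == "captured") res$x else NA_real_
  capture_strip <- if (outcome == "captured")
    1L + as.integer(floor(capture_x / g$strip_period)) else NA_integer_
  structure(
    list(outcome = outcome, capture_strip = capture_strip,
         capture_x = capture_x,
         final = list(position = c(res$x, res$z),
                      velocity = c(res$vx, res$vz), time = res$time),
         n_steps = res$n_steps,
         path = as.data.frame(res$path),
         conjugate = conj, dt = p$dt, scheme = p$forward_euler),
    class = "magsort_trajectory"
  )
}

#' Classify a capture outcome into the H/M/L/N fractions
#'
#' Strips 1-9 map to `H`, 10-18 to `M`, 19-27 to `L` (scaled by thirds of
#' `strip_count` for non-default arrays); an uncaptured (passed-through)
#' cell is `N`.
#'
#' @param outcome a `magsort_trajectory`, a strip index (1..strip_count), or
#'   `NA`/`"passed_through"` for an uncaptured cell.
#' @param strip_count number of strips in the array.
#' @return factor with levels `H`, `M`, `L`, `N`.
#' @examples
#' classify(5)  # H
#' classify(14) # M
#' @export
classify <- function(outcome, strip_count = 27L) {
  if (inherits(outcome, "magsort_trajectory")) {
    outcome <- if (outcome$outcome == "captured") outcome$capture_strip
               else NA_integer_
  }
  if (is.character(outcome))
    outcome <- ifelse(outcome == "passed_through", NA_integer_,
                      suppressWarnings(as.integer(outcome)))
  third <- strip_count / 3
  bad <- !is.na(outcome) & (outcome < 1 | outcome > strip_count)
  if (any(bad))
    stop("strip index outside 1..", strip_count, call. = FALSE)
  lab <- ifelse(is.na(outcome), "N",
                ifelse(outcome <= third, "H",
                       ifelse(outcome <= 2 * third, "M", "L")))
  factor(lab, levels = c("H", "M", "L", "N"))
}

#' Static equilibrium profile at floor contact
#'
#' For a cell resting on the channel floor at each axial position, the net
#' axial force `f(x) = F_drag + F_mag,x - mu * N(x)` (drag on the stationary
#' cell at its floor height, axial magnetophoretic force at the bead
#' position, static friction capacity from the vertical pinning force
#' `N = max(0, -F_mag,z)`). Stable stationary positions are the downward
#' zero crossings of `f`, located by bisection to 0.1 um.
#'
#' @param conj a [conjugate()] with `n_b >= 1` (with `n_b = 0` the drag is
#'   never balanced and there are no zeros).
#' @param device a `magsort_device`.
#' @param flow optional prebuilt [build_flow()].
#' @param xlim axial range scanned, m.
#' @param dx scan resolution, m.
#' @return object of class `magsort_equilibrium`: list with `x`, `force`
#'   (N), `stable_zeros` (m).
#' @export
equilibrium_profile <- function(conj, device, flow = build_flow(device),
                                xlim = NULL, dx = 5e-6) {
  g <- device$geometry
  if (is.null(xlim)) xlim <- c(dx, g$sorting_length - dx)
  xs <- seq(xlim[1], xlim[2], by = dx)
  f <- .equilibrium_force(xs, conj, device, flow)
  s <- sign(f)
  idx <- which(s[-length(s)] > 0 & s[-1] <= 0) # downward crossings
  zeros <- vapply(idx, function(i) {
    uniroot(function(x) .equilibrium_force(x, conj, device, flow),
            c(xs[i], xs[i + 1]), tol = 1e-7)$root
  }, numeric(1))
  structure(list(x = xs, force = f, stable_zeros = zeros,
                 conjugate = conj),
            class = "magsort_equilibrium")
}

.equilibrium_force <- function(x, conj, device, flow) {
  R <- conj$radius
  zoff <- -R + device$materials$bead_diameter / 2
  fs <- total_field(x, rep_len(R + zoff, length(x)), device)
  Fm <- magnetophoretic_force(conj, fs)
  drag <- 6 * pi * flow$viscosity * R * flow$profile(R)
  N <- pmax(0, -Fm[, "Fz"])
  drag + Fm[, "Fx"] - device$operating$friction_mu * N
}

#' @export
print.magsort_trajectory <- function(x, ...) {
  cat("Cell trajectory:", x$outcome)
  if (x$outcome == "captured")
    cat(sprintf(" at strip %d (x = %.3f mm, %s fraction)",
                x$capture_strip, x$capture_x * 1e3,
                as.character(classify(x$capture_strip))))
  cat(sprintf("\n  %.0f steps of dt = %g s, final t = %.3f s\n",
              x$n_steps, x$dt, x$final$time))
  invisible(x)
}

#' @export
plot.magsort_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  with(x$path, {
    plot(x * 1e3, z * 1e6, type = "l", xlab = "x (mm)", ylab = "z (um)", ...)
    plot(x * 1e3, vx * 1e3, type = "l", xlab = "x (mm)",
         ylab = "vx (mm/s)", ...)
  })
  invisible(x)
}

#' @export
plot.magsort_equilibrium <- function(x, ...) {
  plot(x$x * 1e3, x$force * 1e12, type = "l", xlab = "x (mm)",
       ylab = "net axial force (pN)", ...)
  graphics::abline(h = 0, lty = 2)
  graphics::points(x$stable_zeros * 1e3,
                   rep(0, length(x$stable_zeros)), pch = 19, col = 2)
  invisible(x)
}
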