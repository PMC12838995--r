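# Laminar channel flow: plane-Poiseuille axial profile, sheath-flow sample
# confinement by volumetric flux split, residence/throughput arithmetic and
# Stokes drag. The 40:1 channel aspect ratio makes parallel-plate flow an
# excellent approximation along the center of the channel.

#' Build the channel flow field
#'
#' Plane-Poiseuille profile `u(z) = 6 u_mean (z/h)(1 - z/h)` with
#' `u_mean = Q_total / (width * height)`, plus the sheath-flow sample band
#' (see [sample_band()]).
#'
#' @param device a `magsort_device`.
#' @return object of class `magsort_flow`: list with `Q_total` (m^3/s),
#'   `mean_velocity` (m/s), `profile` (function z -> m/s), `sample_band`
#'   (c(z_low, z_high), m), `channel_height`, `viscosity`.
#' @examples
#' fl <- build_flow(default_device())
#' fl$mean_velocity # ~2.8e-3 m/s
#' @export
build_flow <- function(device) {
  g <- device$geometry; o <- device$operating
  Q <- o$Q_sample + o$Q_buffer
  if (Q <= 0) stop("total flow rate must be positive", call. = FALSE)
  h <- g$channel_height
  u_mean <- Q / (g$channel_width * h)
  structure(
    list(
      Q_total = Q,
      mean_velocity = u_mean,
      profile = function(z) 6 * u_mean * (z / h) * (1 - z / h),
      sample_band = sample_band(device),
      channel_height = h,
      viscosity = device$materials$fluid_viscosity
    ),
    class = "magsort_flow"
  )
}

#' Residence time in the sorting zone
#'
#' `sorting_length / mean_velocity`: the mean transit time of the sorting
#' zone (~10 s for the default device, ~12 s in blood mode).
#'
#' @param device a `magsort_device`.
#' @param flow optionally a prebuilt [build_flow()] object.
#' @return time, s.
#' @export
residence_time <- function(device, flow = build_flow(device)) {
  if (flow$mean_velocity <= 0) stop("mean velocity must be > 0",
                                    call. = FALSE)
  device$geometry$sorting_length / flow$mean_velocity
}

# cumulative flux fraction through [0, z] of the plane-Poiseuille profile
.flux_cdf <- function(s) 3 * s^2 - 2 * s^3

#' Sheath-flow sample band
#'
#' Vertical interval carrying the sample: the band through which the
#' Poiseuille volumetric flux equals `Q_sample / Q_total`, centered on the
#' flux median of the channel (a flux-split model of the co-flowing
#' sample/buffer interface).
#'
#' @param device a `magsort_device`.
#' @return `c(z_low, z_high)` in m.
#' @export
sample_band <- function(device) {
  o <- device$operating
  Q <- o$Q_sample + o$Q_buffer
  if (o$Q_sample <= 0) stop("Q_sample must be > 0", call. = FALSE)
  if (o$Q_sample > Q) stop("Q_sample cannot exceed total flow", call. = FALSE)
  q <- o$Q_sample / Q
  h <- device$geometry$channel_height
  inv <- function(fr) {
    if (fr <= 0) return(0)
    if (fr >= 1) return(1)
    uniroot(function(s) .flux_cdf(s) - fr, c(0, 1), tol = 1e-14)$root
  }
  c(inv(0.5 - q / 2), inv(0.5 + q / 2)) * h
}

#' Stokes drag on a sphere
#'
#' `F = 6 pi eta R (v_fluid - v_cell)`, applied component-wise.
#'
#' @param v_cell,v_fluid velocity vectors (or matrices, row-wise), m/s.
#' @param radius sphere radius, m.
#' @param viscosity dynamic viscosity, Pa.s.
#' @return force, N, same shape as the inputs.
#' @export
drag_force <- function(v_cell, v_fluid, radius, viscosity) {
  if (any(radius <= 0)) stop("radius must be > 0", call. = FALSE)
  6 * pi * viscosity * radius * (v_fluid - v_cell)
}

#' Nominal cell throughput
#'
#' `concentration x Q_total`, the convention under which a 2e5 cells/mL
#' sample at 4 mL/h total flow corresponds to 8e5 cells/h.
#'
#' @param device a `magsort_device`.
#' @param concentration cells per mL.
#' @return cells per hour.
#' @export
throughput <- function(device, concentration) {
  if (any(concentration < 0)) stop("concentration must be >= 0",
                                   call. = FALSE)
  o <- device$operating
  Q_mL_h <- .si_to_ulh(o$Q_sample + o$Q_buffer) / 1e3
  concentration * Q_mL_h
}

#' Run time for a sample aliquot
#'
#' Time to push `volume_mL` through the device at the total flow rate.
#'
#' @param device a `magsort_device`.
#' @param volume_mL aliquot volume, mL.
#' @return time, h.
#' @export
run_time <- function(device, volume_mL) {
  o <- device$operating
  volume_mL / (.si_to_ulh(o$Q_sample + o$Q_buffer) / 1e3)
}

#' @export
print.magsort_flow <- function(x, ...) {
  cat(sprintf(
    "Channel flow: Q_total %.0f uL/h, mean velocity %.2f mm/s\n",
    .si_to_ulh(x$Q_total), x$mean_velocity * 1e3))
  cat(sprintf("  sample band: %.1f to %.1f um of %.0f um channel height\n",
              x$sample_band[1] * 1e6, x$sample_band[2] * 1e6,
              x$channel_height * 1e6))
  invisible(x)
}
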