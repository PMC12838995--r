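# Bead-cell conjugate model and the magnetophoretic force.
#
# A cell carrying n_b superparamagnetic beads is treated as a sphere of the
# cell's size whose magnetic moment is that of its beads; the per-bead force
# is F = n_b mu0 V_b [3(chi_b - chi_f)/((chi_b - chi_f) + 3)] (H.grad)H,
# the susceptibility-contrast form with the Clausius-Mossotti-style shape
# factor.

# shape factor 3*dchi/(dchi + 3)
.shape_factor <- function(materials) {
  dchi <- materials$chi_bead - materials$chi_fluid
  3 * dchi / (dchi + 3)
}

#' Effective susceptibility of a bead-cell conjugate
#'
#' The bead moment diluted over the conjugate volume:
#' `chi_eff = n_b V_b chi_b / (V_cell + n_b V_b)`. Zero iff `n_b = 0`,
#' increasing in `n_b` at fixed size and decreasing in cell size at fixed
#' `n_b`: larger cells attenuate the contribution of a fixed bead load.
#'
#' @param cell_diameter cell diameter, m (0 for a free bead).
#' @param n_b number of bound beads (>= 0).
#' @param materials the `materials` element of a device.
#' @return dimensionless volume susceptibility.
#' @examples
#' conjugate_susceptibility(15e-6, 5, default_device()$materials) # ~2.2e-2
#' @export
conjugate_susceptibility <- function(cell_diameter, n_b, materials) {
  if (any(n_b < 0) || any(cell_diameter < 0))
    stop("n_b and cell_diameter must be >= 0", call. = FALSE)
  Vb <- .sphere_vol(materials$bead_diameter)
  Vc <- .sphere_vol(cell_diameter)
  ifelse(n_b == 0, 0, n_b * Vb * materials$chi_bead / (Vc + n_b * Vb))
}

#' Construct a bead-cell conjugate
#'
#' @param cell_diameter cell diameter, m; 0 builds a free (unbound) bead
#'   with `n_b >= 1`.
#' @param n_b number of bound beads.
#' @param materials the `materials` element of a device.
#' @return object of class `magsort_conjugate` with fields `cell_diameter`,
#'   `n_b`, `bead_volume`, `chi_b`, `chi_f`, `effective_susceptibility`,
#'   `mass` (kg), `radius` (m; the cell radius, or the bead radius for a
#'   free bead).
#' @export
conjugate <- function(cell_diameter, n_b, materials) {
  if (n_b < 0) stop("n_b must be >= 0", call. = FALSE)
  if (cell_diameter <= 0 && n_b < 1)
    stop("a free bead requires n_b >= 1", call. = FALSE)
  Vb <- .sphere_vol(materials$bead_diameter)
  Vc <- .sphere_vol(cell_diameter)
  radius <- if (cell_diameter > 0) cell_diameter / 2 else
    materials$bead_diameter / 2
  structure(
    list(
      cell_diameter = cell_diameter,
      n_b = as.numeric(n_b),
      bead_volume = Vb,
      chi_b = materials$chi_bead,
      chi_f = materials$chi_fluid,
      effective_susceptibility =
        conjugate_susceptibility(cell_diameter, n_b, materials),
      mass = materials$cell_density * (Vc + n_b * Vb),
      radius = radius,
      shape_factor = .shape_factor(materials)
    ),
    class = "magsort_conjugate"
  )
}

#' Magnetophoretic force on a conjugate
#'
#' `F = n_b mu0 V_b [3 dchi/(dchi + 3)] (H.grad)H` with
#' `dchi = chi_b - chi_f`, evaluated at the supplied field sample(s);
#' direction parallel to the force factor. Exactly linear in `n_b`.
#'
#' @param conj a [conjugate()].
#' @param sample a `magsort_field` frame from [total_field()] (columns
#'   `ffx`, `ffz`), or a 2-column matrix of force-factor components.
#' @return matrix with columns `Fx`, `Fz`, N.
#' @export
magnetophoretic_force <- function(conj, sample) {
  ff <- if (is.data.frame(sample)) cbind(sample$ffx, sample$ffz)
        else matrix(sample, ncol = 2)
  coef <- conj$n_b * .mu0 * conj$bead_volume *
    3 * (conj$chi_b - conj$chi_f) / ((conj$chi_b - conj$chi_f) + 3)
  out <- coef * ff
  colnames(out) <- c("Fx", "Fz")
  out
}

#' Contact friction force (axial)
#'
#' Coulomb friction of a cell pressed onto the channel floor with normal
#' force `F_normal`. Moving (`|v_axial| > eps`): dynamic friction
#' `-sign(v) mu F_normal`. Static (`|v_axial| <= eps`): opposes the applied
#' axial force up to the capacity `mu F_normal`, so the cell remains
#' stationary iff `|F_applied_axial| <= mu F_normal`.
#'
#' @param F_normal magnitude of the pinning force, N (>= 0).
#' @param mu friction coefficient.
#' @param v_axial axial velocity, m/s.
#' @param F_applied_axial applied axial force excluding friction, N.
#' @param eps static/dynamic velocity threshold, m/s.
#' @return axial friction force, N.
#' @export
friction_force <- function(F_normal, mu, v_axial, F_applied_axial,
                           eps = 1e-7) {
  if (any(F_normal < 0)) stop("F_normal must be >= 0", call. = FALSE)
  ifelse(abs(v_axial) > eps,
         -sign(v_axial) * mu * F_normal,
         -sign(F_applied_axial) * pmin(abs(F_applied_axial), mu * F_normal))
}

#' Parametric sweep of conjugate susceptibility
#'
#' Effective susceptibility over a grid of cell diameters and bead counts,
#' for parametric plots of how cell volume dilutes a fixed bead load.
#'
#' @param diameters cell diameters, m.
#' @param n_b bead counts.
#' @param materials the `materials` element of a device.
#' @return long data.frame with `cell_diameter`, `n_b`, `chi_eff`.
#' @export
susceptibility_sweep <- function(diameters, n_b, materials) {
  grid <- expand.grid(cell_diameter = diameters, n_b = n_b)
  grid$chi_eff <- conjugate_susceptibility(grid$cell_diameter, grid$n_b,
                                           materials)
  grid
}

#' @export
print.magsort_conjugate <- function(x, ...) {
  if (x$cell_diameter > 0)
    cat(sprintf("Bead-cell conjugate: %.1f um cell, %g bead(s), chi_eff %.3g\n",
                x$cell_diameter * 1e6, x$n_b, x$effective_susceptibility))
  else
    cat(sprintf("Free bead (x%g), chi_eff %.3g\n", x$n_b,
                x$effective_susceptibility))
  invisible(x)
}
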