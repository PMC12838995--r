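# Sculpted magnetic field of the strip array in the decaying background
# field: B, grad|B| and the magnetophoretic force factor (H.grad)H anywhere
# outside the strip bodies.
#
# Each strip is a uniformly x-magnetized rectangle, represented by equivalent
# magnetic surface-charge sheets on its two x-edges; the closed-form field
# (arctan/log) and its analytic Jacobian are evaluated in compiled code.
# Strips are magnetized single-pass by the background field at their centers
# (no strip-strip coupling).

#' Background-field decay exponent
#'
#' The background field along the channel is modelled as a power law
#' `B(x) = B_last * ((x_m - L)/(x_m - x))^p` anchored at the magnet face
#' `x_m` and calibrated so that both printed endpoints (inlet and last
#' strip) are matched exactly. This returns the solved exponent `p`.
#'
#' @param device a `magsort_device`.
#' @return the exponent, dimensionless.
#' @export
background_exponent <- function(device) {
  o <- device$operating; g <- device$geometry
  log(o$B_at_last_strip / o$B_at_inlet) /
    log(g$magnet_face_x / (g$magnet_face_x - g$sorting_length))
}

#' Background field along the sorting zone
#'
#' x-directed background flux density at axial position `x`, monotone
#' increasing from `B_at_inlet` at x = 0 to `B_at_last_strip` at the end of
#' the sorting zone.
#'
#' @param x axial position(s), m, inside `[0, sorting_length]`.
#' @param device a `magsort_device`.
#' @return flux density, T.
#' @export
background_field <- function(x, device) {
  g <- device$geometry; o <- device$operating
  if (any(x < 0 | x > g$sorting_length))
    stop("x outside the sorting zone [0, ", g$sorting_length, "] m",
         call. = FALSE)
  p <- background_exponent(device)
  o$B_at_last_strip *
    ((g$magnet_face_x - g$sorting_length) / (g$magnet_face_x - x))^p
}

#' In-plane demagnetizing factor of the strip cross-section
#'
#' Thin-rectangle approximation `N = (2/pi) atan(t/w)` for magnetization
#' along the strip width `w` with thickness `t` (exact 0.5 in the square
#' limit, ~2t/(pi w) for thin strips).
#'
#' @param geometry the `geometry` element of a device.
#' @return dimensionless demagnetizing factor.
#' @export
demag_factor <- function(geometry) {
  (2 / pi) * atan(geometry$strip_thickness / geometry$strip_width)
}

#' Strip magnetization at a local background field
#'
#' Magnetization (along +x) of a soft-magnetic strip exposed to a local flux
#' density `B_local`. With `demag_N = 0` this is the bare apparent-
#' susceptibility law `M = min(chi_app * H, Ms)` with
#' `chi_app = mu_r_initial - 1` and `Ms = saturation_polarization / mu0`;
#' with a positive demagnetizing factor the internal field is shape-limited,
#' `M = min(H / (demag_N + 1/chi_app), Ms)`. Continuous and monotone
#' non-decreasing in `B_local`.
#'
#' @param B_local local background flux density, T.
#' @param materials the `materials` element of a device.
#' @param demag_N in-plane demagnetizing factor (0 disables the correction).
#' @return magnetization, A/m.
#' @export
strip_magnetization <- function(B_local, materials, demag_N = 0) {
  chi_app <- materials$mu_r_initial - 1
  Ms <- materials$saturation_polarization / .mu0
  H <- abs(B_local) / .mu0
  pmin(H / (demag_N + 1 / chi_app), Ms)
}

#' Strip sources of a device
#'
#' One row per strip: extent, and the magnetization induced single-pass by
#' the background field at the strip center. When `materials$demag` is TRUE
#' (the default device) the in-plane demagnetizing factor of
#' [demag_factor()] limits the magnetization; strips near the high-field end
#' reach saturation.
#'
#' @param device a `magsort_device`.
#' @return data.frame with columns `index`, `x_left`, `x_right`, `z_bottom`,
#'   `z_top`, `magnetization` (SI).
#' @export
strip_sources <- function(device) {
  g <- device$geometry
  i <- seq_len(g$strip_count)
  widths <- rep_len(if (is.null(g$strip_widths)) g$strip_width
                    else g$strip_widths, g$strip_count)
  if (any(widths <= 0) || any(widths > g$strip_period))
    stop("invalid device configuration: `strip_widths` must lie in ",
         "(0, strip_period]", call. = FALSE)
  centers <- (i - 1) * g$strip_period + g$strip_period / 2
  ext <- cbind(centers - widths / 2, centers + widths / 2)
  N <- if (isTRUE(device$materials$demag))
    (2 / pi) * atan(g$strip_thickness / widths) else 0
  M <- strip_magnetization(background_field(centers, device),
                           device$materials, demag_N = N)
  data.frame(index = i, x_left = ext[, 1], x_right = ext[, 2],
             z_bottom = -g$gap_D - g$strip_thickness, z_top = -g$gap_D,
             magnetization = M)
}

# strips as the 5-column matrix the compiled code expects
.strip_matrix <- function(strips) {
  as.matrix(strips[, c("x_left", "x_right", "z_bottom", "z_top",
                       "magnetization")])
}

.inside_strip <- function(strips, x, z) {
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nrow(strips))) {
    inside <- inside |
      (x >= strips$x_left[k] & x <= strips$x_right[k] &
         z >= strips$z_bottom[k] & z <= strips$z_top[k])
  }
  inside
}

#' Field of a single magnetized strip
#'
#' Closed-form 2D flux density of one uniformly x-magnetized rectangle at
#' points outside its body (equivalent surface-charge sheets on the two
#' x-edges). Superposition over strips is exact.
#'
#' @param strip a single row of [strip_sources()] (or any list with
#'   `x_left`, `x_right`, `z_bottom`, `z_top`, `magnetization`).
#' @param x,z evaluation point(s), m.
#' @return matrix with columns `Bx`, `Bz` (T).
#' @export
strip_field <- function(strip, x, z) {
  strip <- as.data.frame(strip)[1, , drop = FALSE]
  if (any(.inside_strip(strip, x, z)))
    stop("evaluation point inside the strip body", call. = FALSE)
  f <- cpp_field(x, z, .strip_matrix(strip), 0, 1, 1, 0.5)
  f[, c("Bx", "Bz"), drop = FALSE]
}

#' Total field sample
#'
#' Background plus all strip contributions at the requested points: flux
#' density, gradient of |B|, and the magnetophoretic force factor
#' `(H . grad) H` (equal to `grad(|H|^2)/2` in this current-free region).
#' Gradients come from the analytic Jacobian of the closed-form field.
#'
#' @param x,z evaluation point(s), m, outside the strip bodies.
#' @param device a `magsort_device`.
#' @return data.frame of class `magsort_field` with columns `x`, `z`, `Bx`,
#'   `Bz`, `B`, `dBdx`, `dBdz` (grad|B|, T/m) and `ffx`, `ffz` (force
#'   factor, A^2 m^-3).
#' @export
total_field <- function(x, z, device) {
  n <- max(length(x), length(z))
  x <- rep_len(x, n); z <- rep_len(z, n)
  strips <- strip_sources(device)
  if (any(.inside_strip(strips, x, z)))
    stop("evaluation point inside a strip body", call. = FALSE)
  g <- device$geometry; o <- device$operating
  f <- cpp_field(x, z, .strip_matrix(strips), o$B_at_last_strip,
                 background_exponent(device), g$magnet_face_x,
                 g$sorting_length)
  .field_frame(x, z, f)
}

# assemble the FieldSample frame from the raw B/Jacobian matrix
.field_frame <- function(x, z, f) {
  Bx <- f[, "Bx"]; Bz <- f[, "Bz"]
  B <- sqrt(Bx^2 + Bz^2)
  # grad|B| = J^T B / |B|
  dBdx <- (Bx * f[, "dBxdx"] + Bz * f[, "dBzdx"]) / B
  dBdz <- (Bx * f[, "dBxdz"] + Bz * f[, "dBzdz"]) / B
  # (H.grad)H = J_H H, with H = B/mu0
  ffx <- (f[, "dBxdx"] * Bx + f[, "dBxdz"] * Bz) / .mu0^2
  ffz <- (f[, "dBzdx"] * Bx + f[, "dBzdz"] * Bz) / .mu0^2
  structure(
    data.frame(x = x, z = z, Bx = Bx, Bz = Bz, B = B,
               dBdx = dBdx, dBdz = dBdz, ffx = ffx, ffz = ffz),
    class = c("magsort_field", "data.frame")
  )
}

#' Field map on a rectilinear grid
#'
#' Deterministic grid evaluation of [total_field()].
#'
#' @param device a `magsort_device`.
#' @param xlim,zlim domain bounds, m. Defaults: the sorting zone at channel
#'   heights `[0, channel_height]`.
#' @param nx,nz nodes per axis (>= 2).
#' @return a `magsort_field_map`: the [total_field()] frame over the grid,
#'   with attributes `x_grid`, `z_grid` and `device`.
#' @export
field_map <- function(device, xlim = NULL, zlim = NULL, nx = 101, nz = 11) {
  g <- device$geometry
  if (is.null(xlim)) xlim <- c(0, g$sorting_length)
  if (is.null(zlim)) zlim <- c(0, g$channel_height)
  if (nx < 2 || nz < 2) stop("resolution must be >= 2 nodes per axis",
                             call. = FALSE)
  xs <- seq(xlim[1], xlim[2], length.out = nx)
  zs <- seq(zlim[1], zlim[2], length.out = nz)
  grid <- expand.grid(x = xs, z = zs)
  fm <- total_field(grid$x, grid$z, device)
  structure(fm, x_grid = xs, z_grid = zs, device = device,
            class = c("magsort_field_map", class(fm)))
}

#' Peak field gradient near a strip edge
#'
#' Maximum |grad|B|| over an arc of radius `r` centered on the top corner of
#' a strip edge (both corners scanned; points inside the strip body are
#' skipped). This probes the high-gradient capture zone that the strip edge
#' sculpts out of the background field.
#'
#' @param device a `magsort_device`.
#' @param strip_index which strip (default: the last, highest-field strip).
#' @param r arc radius, m.
#' @param n_theta arc sample count.
#' @return list with `max_grad` (T/m), `n` (points evaluated), and the
#'   scanned data.frame.
#' @export
edge_gradient_scan <- function(device, strip_index = NULL, r = 50e-6,
                               n_theta = 721) {
  g <- device$geometry
  if (is.null(strip_index)) strip_index <- g$strip_count
  ext <- .strip_extent(g, strip_index)
  ztop <- -g$gap_D
  theta <- seq(0, 2 * pi, length.out = n_theta)
  pts <- do.call(rbind, lapply(ext, function(xc) {
    data.frame(x = xc + r * cos(theta), z = ztop + r * sin(theta))
  }))
  strips <- strip_sources(device)
  pts <- pts[!.inside_strip(strips, pts$x, pts$z), ]
  fs <- total_field(pts$x, pts$z, device)
  gmag <- sqrt(fs$dBdx^2 + fs$dBdz^2)
  list(max_grad = max(gmag), n = nrow(pts),
       scan = cbind(pts, grad = gmag))
}

#' Peak field gradient on a line above a strip
#'
#' Maximum |grad|B|| along the horizontal line `height` above the strip
#' tops, across one strip period centered on `strip_index`.
#'
#' @inheritParams edge_gradient_scan
#' @param height height above the strip tops, m.
#' @param n_x samples along the line.
#' @return list with `max_grad` (T/m), `n`, and the scanned data.frame.
#' @export
line_gradient_scan <- function(device, strip_index = NULL, height = 10e-6,
                               n_x = 1001) {
  g <- device$geometry
  if (is.null(strip_index)) strip_index <- g$strip_count
  ext <- .strip_extent(g, strip_index)
  xc <- mean(ext)
  xs <- seq(xc - g$strip_period / 2, xc + g$strip_period / 2,
            length.out = n_x)
  xs <- pmin(xs, g$sorting_length) # stay inside the background domain
  fs <- total_field(xs, rep(-g$gap_D + height, n_x), device)
  gmag <- sqrt(fs$dBdx^2 + fs$dBdz^2)
  list(max_grad = max(gmag), n = n_x,
       scan = data.frame(x = xs, grad = gmag))
}

#' @export
plot.magsort_field_map <- function(x, what = "B", ...) {
  xs <- attr(x, "x_grid"); zs <- attr(x, "z_grid")
  m <- matrix(x[[what]], nrow = length(xs))
  graphics::image(xs * 1e3, zs * 1e6, m, xlab = "x (mm)", ylab = "z (um)",
                  main = paste("field map:", what), ...)
  invisible(x)
}
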