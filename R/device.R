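# Device geometry, material properties and operating point.
#
# All values are stored in SI units (m, T, Pa.s, m^3/s). Configuration files
# use the bench units common in the microfluidics literature (um, mm, mT,
# uL/h) and are converted on load; see `load_config()` for the schema.

# unit scale applied when reading a config value (config unit -> SI)
.cfg_units <- list(
  geometry = c(
    strip_count = 1, strip_width = 1e-6, strip_period = 1e-6,
    strip_thickness = 1e-6, strip_span_y = 1e-3, gap_D = 1e-6,
    channel_height = 1e-6, channel_width = 1e-3, sorting_length = 1e-3,
    magnet_face_x = 1e-3
  ),
  materials = c(
    mu_r_initial = 1, mu_r_max = 1, saturation_polarization = 1,
    chi_bead = 1, chi_fluid = 1, bead_diameter = 1e-6, fluid_viscosity = 1,
    cell_density = 1, fluid_density = 1, demag = 1
  ),
  operating = c(
    Q_sample = 1e-9 / 3600, Q_buffer = 1e-9 / 3600, B_at_inlet = 1e-3,
    B_at_last_strip = 1e-3, friction_mu = 1, dt = 1, max_time = 1
  )
)

#' Default sorting device
#'
#' Returns the reference 27-strip device: 500 um wide, 35 um thick
#' soft-magnetic strips on a 1 mm pitch spanning a 27 mm sorting zone, a
#' 4 mm x 100 um channel separated from the strip tops by a 50 um gap, and a
#' laterally decaying background field calibrated to 9 mT at the inlet and
#' 35 mT at the last strip (magnet face at x = 45 mm).
#'
#' @param mode `"pbs"` (sample 3000 uL/h, buffer 1000 uL/h, viscosity
#'   1.0 mPa.s) or `"blood"` (2500 / 800 uL/h, 3.5 mPa.s, blood modelled
#'   solely as elevated viscosity).
#' @return An object of class `magsort_device`: a list with elements
#'   `geometry`, `materials` and `operating`, all in SI units.
#' @examples
#' dev <- default_device()
#' dev$geometry$strip_count
#' @export
default_device <- function(mode = c("pbs", "blood")) {
  mode <- match.arg(mode)
  geometry <- list(
    strip_count = 27L,
    strip_width = 500e-6,
    strip_period = 1000e-6,
    strip_thickness = 35e-6,
    strip_span_y = 3e-3,
    gap_D = 50e-6,
    channel_height = 100e-6,
    channel_width = 4e-3,
    sorting_length = 27e-3,
    magnet_face_x = 45e-3
  )
  materials <- list(
    mu_r_initial = 8e4,
    mu_r_max = 2e5,
    saturation_polarization = 0.75, # T; annealed permalloy-class default
    chi_bead = 0.7,                 # SI volume susceptibility, 2.8 um beads
    chi_fluid = -9.0e-6,
    bead_diameter = 2.8e-6,
    fluid_viscosity = if (mode == "pbs") 1.0e-3 else 3.5e-3,
    cell_density = 1050,
    fluid_density = 1000,
    demag = TRUE # in-plane demagnetization-limited strip magnetization
  )
  operating <- list(
    Q_sample = .ulh_to_si(if (mode == "pbs") 3000 else 2500),
    Q_buffer = .ulh_to_si(if (mode == "pbs") 1000 else 800),
    B_at_inlet = 9e-3,
    B_at_last_strip = 35e-3,
    friction_mu = 0.10,
    dt = 1e-5,
    max_time = 30
  )
  dev <- structure(
    list(geometry = geometry, materials = materials, operating = operating,
         mode = mode),
    class = "magsort_device"
  )
  validate_device(dev)
  dev
}

#' Validate a device configuration
#'
#' Checks every declared invariant of the geometry, material and operating
#' blocks and stops with an error naming the offending field.
#'
#' @param device a `magsort_device` object.
#' @return the device, invisibly, if valid.
#' @export
validate_device <- function(device) {
  g <- device$geometry; m <- device$materials; o <- device$operating
  fail <- function(field, why) {
    stop("invalid device configuration: `", field, "` ", why, call. = FALSE)
  }
  chk_pos <- function(block, fields) {
    for (f in fields) {
      v <- block[[f]]
      if (is.null(v) || !is.finite(v) || v <= 0) fail(f, "must be > 0")
    }
  }
  chk_pos(g, c("strip_count", "strip_width", "strip_period", "strip_thickness",
               "strip_span_y", "gap_D", "channel_height", "channel_width",
               "sorting_length", "magnet_face_x"))
  if (abs(g$strip_count * g$strip_period - g$sorting_length) >
      1e-9 * g$sorting_length)
    fail("sorting_length", "must equal strip_count * strip_period")
  if (g$strip_width > g$strip_period)
    fail("strip_width", "must not exceed strip_period")
  if (g$magnet_face_x <= g$sorting_length)
    fail("magnet_face_x", "must exceed sorting_length")
  chk_pos(m, c("mu_r_initial", "mu_r_max", "saturation_polarization",
               "chi_bead", "bead_diameter", "fluid_viscosity", "cell_density",
               "fluid_density"))
  if (!is.finite(m$chi_fluid) || abs(m$chi_fluid) >= m$chi_bead)
    fail("chi_fluid", "must satisfy |chi_fluid| << chi_bead")
  for (f in c("Q_sample", "Q_buffer"))
    if (!is.finite(o[[f]]) || o[[f]] < 0) fail(f, "must be >= 0")
  if (!(o$B_at_last_strip > o$B_at_inlet && o$B_at_inlet > 0))
    fail("B_at_last_strip", "must satisfy B_at_last_strip > B_at_inlet > 0")
  if (!is.finite(o$friction_mu) || o$friction_mu < 0.05 || o$friction_mu > 0.15)
    fail("friction_mu", "must lie in [0.05, 0.15]")
  if (!is.finite(o$dt) || o$dt <= 0) fail("dt", "must be > 0")
  if (!is.finite(o$max_time) || o$max_time <= 0) fail("max_time", "must be > 0")
  invisible(device)
}

#' Load a device configuration file
#'
#' Reads a YAML file with (optional) top-level blocks `geometry`, `materials`
#' and `operating`, whose keys match the field names of [default_device()].
#' Values are given in bench units: lengths in um (`strip_span_y`,
#' `channel_width`, `sorting_length`, `magnet_face_x` in mm), fields in mT
#' (`saturation_polarization` in T), flows in uL/h, viscosity in Pa.s, times
#' in s. Unspecified fields take the mode defaults; every override is
#' reported via [message()].
#'
#' @param path path to a YAML configuration file.
#' @param mode base mode supplying defaults, as in [default_device()].
#' @return a validated `magsort_device`.
#' @export
load_config <- function(path, mode = c("pbs", "blood")) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  dev <- default_device(mode)
  for (block in names(.cfg_units)) {
    if (is.null(cfg[[block]])) next
    units <- .cfg_units[[block]]
    for (key in names(cfg[[block]])) {
      if (!key %in% names(units))
        stop("unknown configuration key `", block, "$", key, "`",
             call. = FALSE)
      raw <- cfg[[block]][[key]]
      val <- if (key == "demag") isTRUE(raw) else raw * units[[key]]
      if (key == "strip_count") val <- as.integer(val)
      message("config override: ", block, "$", key, " = ", format(raw))
      dev[[block]][[key]] <- val
    }
  }
  validate_device(dev)
  dev
}

#' Write a device configuration file
#'
#' Serializes a device to the YAML schema read by [load_config()] (bench
#' units). Loading the written file reproduces the device field-for-field.
#'
#' @param device a `magsort_device`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(device, path) {
  out <- list()
  for (block in names(.cfg_units)) {
    units <- .cfg_units[[block]]
    vals <- device[[block]][names(units)[names(units) %in%
                                           names(device[[block]])]]
    out[[block]] <- lapply(names(vals), function(key) {
      if (key == "demag") return(isTRUE(vals[[key]]))
      vals[[key]] / units[[key]]
    })
    names(out[[block]]) <- names(vals)
  }
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.magsort_device <- function(x, ...) {
  g <- x$geometry; o <- x$operating; m <- x$materials
  cat("Strip-array magnetophoretic sorting device (", x$mode, " mode)\n",
      sep = "")
  cat(sprintf("  strips: %d x %.0f um wide, %.0f um thick, %.0f um pitch\n",
              g$strip_count, g$strip_width * 1e6, g$strip_thickness * 1e6,
              g$strip_period * 1e6))
  cat(sprintf("  channel: %.1f mm x %.0f um, gap to strips %.0f um\n",
              g$channel_width * 1e3, g$channel_height * 1e6, g$gap_D * 1e6))
  cat(sprintf("  background field: %.1f mT (inlet) to %.1f mT (last strip)\n",
              o$B_at_inlet * 1e3, o$B_at_last_strip * 1e3))
  cat(sprintf("  flow: sample %.0f + buffer %.0f uL/h, viscosity %.2g Pa.s\n",
              .si_to_ulh(o$Q_sample), .si_to_ulh(o$Q_buffer),
              m$fluid_viscosity))
  invisible(x)
}

#' Apply fabrication jitter to the strip widths
#'
#' Perturbs each strip width independently and uniformly by up to
#' `+/- frac` of nominal (the within-lot tolerance of the lithography-etch
#' process), keeping strips centered on their period centers. Used for
#' robustness checks of the fractionation against fabrication spread.
#'
#' @param device a `magsort_device`.
#' @param frac maximum relative deviation (default 0.10).
#' @param seed integer seed for the draws.
#' @return the device with a per-strip `geometry$strip_widths` vector.
#' @export
jitter_strip_widths <- function(device, frac = 0.10, seed = 1L) {
  set.seed(seed)
  n <- device$geometry$strip_count
  device$geometry$strip_widths <-
    device$geometry$strip_width * runif(n, 1 - frac, 1 + frac)
  device
}

# x-interval occupied by strip i (1-based from the inlet)
.strip_extent <- function(geometry, i) {
  x0 <- (i - 1) * geometry$strip_period
  c(x0 + (geometry$strip_period - geometry$strip_width) / 2,
    x0 + (geometry$strip_period + geometry$strip_width) / 2)
}
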