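# Deterministic tabular output, run manifests, and the gap/field
# compensation sweep used to pick operating points.

#' Write a numeric table losslessly
#'
#' Comma-separated text with a header row; numeric columns are written with
#' 17 significant digits so that re-parsing recovers the doubles exactly.
#' Unit annotations go into `#`-prefixed comment lines above the header.
#'
#' @param df data.frame.
#' @param path output path.
#' @param units optional character vector of unit annotations, one per
#'   column.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units))
    writeLines(paste0("# units: ",
                      paste(names(df), units, sep = "=", collapse = ", ")),
               con)
  fmt <- vapply(df, function(col) {
    if (is.double(col)) formatC(col, digits = 17, format = "g")
    else as.character(col)
  }, character(nrow(df)))
  fmt <- matrix(fmt, nrow = nrow(df))
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(apply(fmt, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_table_file <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write a field map as tabular text
#'
#' Columns: x, z, Bx, Bz, |B|, d|B|/dx, d|B|/dz and the force-factor
#' components, with units named in the header comment.
#'
#' @param fm a [field_map()] (or [total_field()]) frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field_map <- function(fm, path) {
  write_table(as.data.frame(fm), path,
              units = c("m", "m", "T", "T", "T", "T/m", "T/m",
                        "A^2/m^3", "A^2/m^3"))
}

#' Write a run manifest
#'
#' One JSON record per run with the command, the fully resolved
#' configuration, seed(s), package version, output files and wall time --
#' sufficient to reproduce the run.
#'
#' @param path output path (JSON).
#' @param command character description of the invocation.
#' @param device the resolved `magsort_device`.
#' @param seed seed(s) used.
#' @param outputs character vector of files written.
#' @param wall_time elapsed seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, device, seed = NULL,
                           outputs = character(), wall_time = NA_real_) {
  manifest <- list(
    command = command,
    configuration = device[c("geometry", "materials", "operating", "mode")],
    seed = seed,
    package_version = as.character(utils::packageVersion("magsort")),
    outputs = outputs,
    wall_time_s = wall_time
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Gap / background-field compensation sweep
#'
#' Grid evaluation of the peak |grad|B|| at the channel floor above a probe
#' strip, as the strip-channel gap and the background-field scale vary.
#' Raising the background field restores the peak gradient lost to a larger
#' gap, as long as the probe strip stays below saturation; the default
#' probe is a mid-array strip, which has the most field headroom.
#'
#' @param device base `magsort_device`.
#' @param gaps strip-channel gaps to evaluate, m.
#' @param field_scales multipliers applied to both background endpoints.
#' @param strip_index probe strip (default: mid-array).
#' @return data.frame with `gap_D`, `field_scale`, `peak_grad` (T/m).
#' @export
gap_field_sweep <- function(device, gaps = c(50e-6, 60e-6, 70e-6),
                            field_scales = c(1, 1.5, 2),
                            strip_index = NULL) {
  g <- device$geometry
  if (is.null(strip_index)) strip_index <- ceiling(g$strip_count / 2)
  grid <- expand.grid(gap_D = gaps, field_scale = field_scales)
  grid$peak_grad <- vapply(seq_len(nrow(grid)), function(i) {
    dev <- device
    dev$geometry$gap_D <- grid$gap_D[i]
    dev$operating$B_at_inlet <- device$operating$B_at_inlet *
      grid$field_scale[i]
    dev$operating$B_at_last_strip <- device$operating$B_at_last_strip *
      grid$field_scale[i]
    # peak gradient at the channel floor (z = 0), one period about the probe
    line_gradient_scan(dev, strip_index = strip_index,
                       height = dev$geometry$gap_D, n_x = 501)$max_grad
  }, numeric(1))
  grid
}
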