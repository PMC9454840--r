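# Run configuration (YAML), workflow commands and file outputs.
# Config lengths are in mm (the bench-side convention); everything is
# converted to SI on load.

config_schema <- list(
  top = c("geometry", "settings", "solver", "stimulation", "output", "seed"),
  geometry = c("well_diameter_mm", "electrode_gap_mm", "electrode_width_mm",
               "electrode_thickness_mm", "fill_level_mm", "liquid_volume_ml",
               "effective_area_cm2", "conductivity_S_per_m"),
  solver = c("edge_length_mm", "n_profile_samples"),
  stimulation = c("duration_s", "density_kg_per_m3", "heat_capacity_J_per_kgK"),
  setting = c("code", "voltage_V", "frequency_Hz", "pulse_ms")
)

schema_error <- function(path, msg) {
  stop("config error at `", path, "`: ", msg, call. = FALSE)
}

check_keys <- function(x, allowed, path) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    schema_error(paste0(path, ".", unknown[1]), "unknown key")
  }
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration describing the chamber geometry (lengths
#' in mm), the stimulation settings, solver options and stimulation
#' protocol. Unknown keys are rejected. Defaults are the characterized
#' chamber and its four settings.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Class `run_config`: list with `geometry`
#'   (a [chamber_geometry()]), `settings` (named list of
#'   [pulse_waveform()]), `edge_length` (m), `n_profile_samples`,
#'   `duration` (s), `density`, `heat_capacity`, `seed`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) schema_error("", "top level must be a mapping")
  check_keys(raw, config_schema$top, "")

  gsec <- raw$geometry
  geometry <- if (is.null(gsec)) {
    default_chamber()
  } else {
    check_keys(gsec, config_schema$geometry, "geometry")
    d <- default_chamber()
    mm <- function(key, default_m) {
      if (!is.null(gsec[[key]])) gsec[[key]] * 1e-3 else default_m
    }
    fill <- if (!is.null(gsec$fill_level_mm)) {
      gsec$fill_level_mm * 1e-3
    } else if (!is.null(gsec$liquid_volume_ml)) {
      if (is.null(gsec$effective_area_cm2)) {
        schema_error("geometry.effective_area_cm2",
                     "required when fill level is given as a volume")
      }
      fill_level_from_volume(gsec$liquid_volume_ml * 1e-6,
                             gsec$effective_area_cm2 * 1e-4)
    } else {
      d$fill_level
    }
    chamber_geometry(
      well_diameter = mm("well_diameter_mm", d$well_diameter),
      electrode_gap = mm("electrode_gap_mm", d$electrode_gap),
      electrode_width = mm("electrode_width_mm", d$electrode_width),
      electrode_thickness = mm("electrode_thickness_mm",
                               d$electrode_thickness),
      fill_level = fill,
      conductivity = if (!is.null(gsec$conductivity_S_per_m)) {
        gsec$conductivity_S_per_m
      } else {
        d$conductivity
      }
    )
  }

  settings <- if (is.null(raw$settings)) {
    default_settings()
  } else {
    out <- list()
    for (k in seq_along(raw$settings)) {
      s <- raw$settings[[k]]
      check_keys(s, config_schema$setting, sprintf("settings[%d]", k))
      for (key in config_schema$setting) {
        if (is.null(s[[key]])) {
          schema_error(sprintf("settings[%d].%s", k, key), "missing key")
        }
      }
      out[[s$code]] <- pulse_waveform(s$voltage_V, s$frequency_Hz,
                                      s$pulse_ms * 1e-3)
    }
    out
  }

  sv <- raw$solver
  if (!is.null(sv)) check_keys(sv, config_schema$solver, "solver")
  st <- raw$stimulation
  if (!is.null(st)) check_keys(st, config_schema$stimulation, "stimulation")
  pick <- function(sec, key, default) {
    if (!is.null(sec[[key]])) sec[[key]] else default
  }
  structure(
    list(
      geometry = geometry,
      settings = settings,
      edge_length = pick(sv, "edge_length_mm", 0.3) * 1e-3,
      n_profile_samples = pick(sv, "n_profile_samples", 101),
      duration = pick(st, "duration_s", 600),
      density = pick(st, "density_kg_per_m3", 1000),
      heat_capacity = pick(st, "heat_capacity_J_per_kgK", 4184),
      seed = if (!is.null(raw$seed)) raw$seed else 1L
    ),
    class = "run_config"
  )
}

#' Export a solved field as a legacy VTK unstructured grid
#'
#' Writes nodes, triangles, point data `phi` and cell data `E_x`, `E_y`,
#' `E_mag` in ASCII legacy VTK, viewable in ParaView.
#'
#' @param field A [solve_potential()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path) {
  stopifnot(inherits(field, "potential_field"))
  mesh <- field$mesh
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("stimwell potential field (V = %g V)", field$voltage_difference)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", n)
  writeLines(sprintf("%.9e %.9e 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  wl("CELLS %d %d", m, 4L * m)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  wl("CELL_TYPES %d", m)
  writeLines(rep("5", m), con)
  wl("POINT_DATA %d", n)
  wl("SCALARS phi double 1")
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9e", field$phi), con)
  wl("CELL_DATA %d", m)
  emag <- sqrt(field$efield[, 1]^2 + field$efield[, 2]^2)
  for (nm in c("E_x", "E_y", "E_mag")) {
    vals <- switch(nm, E_x = field$efield[, 1], E_y = field$efield[, 2],
                   E_mag = emag)
    wl("SCALARS %s double 1", nm)
    wl("LOOKUP_TABLE default")
    writeLines(sprintf("%.9e", vals), con)
  }
  invisible(path)
}

#' Run the field-simulation workflow
#'
#' Meshes the configured chamber, solves the potential at 1 V, and
#' writes the VTK field export, the centerline profile CSV
#' (`position_mm`, `E_V_per_m`) and the homogeneity CSV (`band_low`,
#' `band_high`, `area_fraction` for the 80/90/100 V/m-per-volt bands
#' scaled to each configured voltage).
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `field`, `profile`, `homogeneity` and
#'   the output paths.
#' @export
run_simulate <- function(config = NULL, out_dir = ".") {
  if (is.null(config)) config <- read_run_config()
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- generate_mesh(config$geometry, config$edge_length)
  field <- solve_potential(mesh, 1)
  profile <- centerline_profile(field, config$n_profile_samples)
  bands <- data.frame(band_low = c(80, 90, 80),
                      band_high = c(90, 100, 100))
  bands$area_fraction <- mapply(
    function(lo, hi) homogeneity_fraction(field, lo, hi),
    bands$band_low, bands$band_high
  )
  vtk <- file.path(out_dir, "field_1V.vtk")
  write_field_vtk(field, vtk)
  prof_csv <- file.path(out_dir, "centerline_profile.csv")
  utils::write.csv(
    data.frame(position_mm = profile$position * 1e3,
               E_V_per_m = profile$e_mag),
    prof_csv, row.names = FALSE
  )
  hom_csv <- file.path(out_dir, "homogeneity.csv")
  utils::write.csv(bands, hom_csv, row.names = FALSE)
  mid <- profile$e_mag[(nrow(profile) + 1) %/% 2]
  message(sprintf("centerline |E| at 1 V: %.1f V/m at the electrode faces, %.1f V/m at the midpoint",
                  profile$e_mag[1], mid))
  invisible(list(field = field, profile = profile, homogeneity = bands,
                 paths = c(vtk = vtk, profile = prof_csv,
                           homogeneity = hom_csv)))
}

#' Run the dose-table workflow
#'
#' Computes the per-setting dose summary (plus the control row) and
#' writes it as CSV.
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param out_dir Output directory.
#' @param measurements Optional measurement data.frame to merge.
#' @return Invisibly, the [dose_table()] data.frame.
#' @export
run_dose <- function(config = NULL, out_dir = ".", measurements = NULL) {
  if (is.null(config)) config <- read_run_config()
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- generate_mesh(config$geometry, config$edge_length)
  field <- solve_potential(mesh, 1)
  tab <- dose_table(config$geometry, config$settings, field,
                    measurements = measurements,
                    duration = config$duration, density = config$density,
                    heat_capacity = config$heat_capacity)
  path <- file.path(out_dir, "dose_table.csv")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(tab)
}

#' Run the model-vs-measurement validation workflow
#'
#' Builds the validation report from a measurement CSV and writes it as
#' CSV plus a plain-text summary. A raised linearity flag is
#' informational, not an error.
#'
#' @param config A [read_run_config()] result (or `NULL` for defaults).
#' @param measurements_csv Path to the measurement CSV (`NULL` for the
#'   packaged fixture).
#' @param out_dir Output directory.
#' @return Invisibly, the [build_validation_report()] result.
#' @export
run_validate <- function(config = NULL, measurements_csv = NULL,
                         out_dir = ".") {
  if (is.null(config)) config <- read_run_config()
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- measured_currents(measurements_csv)
  mesh <- generate_mesh(config$geometry, config$edge_length)
  field <- solve_potential(mesh, 1)
  report <- build_validation_report(config$geometry, field,
                                    config$settings, records)
  utils::write.csv(report$table,
                   file.path(out_dir, "validation_report.csv"),
                   row.names = FALSE)
  txt <- file.path(out_dir, "validation_report.txt")
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(report)
}
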