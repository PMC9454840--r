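#' Chamber geometry for a plate-electrode stimulation well
#'
#' Describes the 2D cross-section (top view) of one well of a 12-well
#' stimulation dish: a circular well containing two parallel plate
#' electrodes, filled with conductive culture medium to a given level.
#' All lengths are SI (metres) internally; configuration files use mm.
#'
#' @param well_diameter Well (dish) inner diameter in m.
#' @param electrode_gap Inner face-to-face electrode spacing d in m.
#' @param electrode_width Plate extent across the well in m.
#' @param electrode_thickness Plate thickness in m.
#' @param fill_level Liquid fill height h in m. If `NULL` it is derived
#'   from `liquid_volume / effective_liquid_area`.
#' @param conductivity Medium conductivity sigma in S/m.
#' @param liquid_volume Optional liquid volume in m^3.
#' @param effective_liquid_area Optional effective horizontal liquid
#'   cross-section in m^2 used to convert volumes to fill levels. The
#'   well is not an ideal cylinder (electrodes, coverslip, meniscus), so
#'   this is a calibration constant rather than `pi * r^2`.
#'
#' @return An object of class `chamber_geometry` (a named list).
#' @seealso [default_chamber()], [generate_mesh()]
#' @export
chamber_geometry <- function(well_diameter,
                             electrode_gap,
                             electrode_width,
                             electrode_thickness,
                             fill_level = NULL,
                             conductivity,
                             liquid_volume = NULL,
                             effective_liquid_area = NULL) {
  if (is.null(fill_level)) {
    if (is.null(liquid_volume) || is.null(effective_liquid_area)) {
      stop("supply `fill_level`, or both `liquid_volume` and ",
           "`effective_liquid_area`", call. = FALSE)
    }
    fill_level <- fill_level_from_volume(liquid_volume, effective_liquid_area)
  }
  geom <- structure(
    list(
      well_diameter = well_diameter,
      electrode_gap = electrode_gap,
      electrode_width = electrode_width,
      electrode_thickness = electrode_thickness,
      fill_level = fill_level,
      conductivity = conductivity,
      liquid_volume = liquid_volume,
      effective_liquid_area = effective_liquid_area
    ),
    class = "chamber_geometry"
  )
  validate_chamber_geometry(geom)
}

#' @rdname chamber_geometry
#' @param geometry A `chamber_geometry` object.
#' @export
validate_chamber_geometry <- function(geometry) {
  g <- geometry
  num <- c(well_diameter = g$well_diameter, electrode_gap = g$electrode_gap,
           electrode_width = g$electrode_width,
           electrode_thickness = g$electrode_thickness,
           fill_level = g$fill_level, conductivity = g$conductivity)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("invalid geometry: all dimensions and the conductivity must be ",
         "finite and positive", call. = FALSE)
  }
  if (g$electrode_gap + 2 * g$electrode_thickness >= g$well_diameter) {
    stop("invalid geometry: electrodes (gap + 2 * thickness) do not fit ",
         "inside the well diameter", call. = FALSE)
  }
  # the plate must fit within the chord of the well circle at the outer face
  r <- g$well_diameter / 2
  offset <- g$electrode_gap / 2 + g$electrode_thickness
  chord <- 2 * sqrt(r^2 - offset^2)
  if (g$electrode_width > chord) {
    stop("invalid geometry: electrode_width exceeds the well chord at the ",
         "electrode position", call. = FALSE)
  }
  if (!is.null(g$liquid_volume) && !is.null(g$effective_liquid_area)) {
    implied <- g$liquid_volume / g$effective_liquid_area
    if (abs(implied - g$fill_level) > 1e-9 + 1e-6 * g$fill_level) {
      stop("invalid geometry: fill_level inconsistent with ",
           "liquid_volume / effective_liquid_area", call. = FALSE)
    }
  }
  geometry
}

#' Reference default stimulation chamber
#'
#' The default reproduces the documented C-Dish style chamber: electrode
#' gap 11 mm, fill level 3.4 mm at 1 mL, one-electrode wetted area
#' 0.42 cm^2 (hence plate width 0.42 cm^2 / 3.4 mm = 12.35 mm), nominal
#' 12-well diameter 22.1 mm, plate thickness 1 mm, medium conductivity
#' 1.3 S/m. The effective liquid area (2.94 cm^2) is the calibration
#' constant that maps 1 mL to the 3.4 mm fill level.
#'
#' @return A `chamber_geometry` object.
#' @export
#' @examples
#' g <- default_chamber()
#' g$electrode_gap                      # 0.011 m
#' wetted_electrode_area(g) * 1e4       # ~0.42 cm^2
default_chamber <- function() {
  fill <- 3.4e-3
  vol <- 1e-6 # 1 mL
  chamber_geometry(
    well_diameter = 22.1e-3,
    electrode_gap = 11e-3,
    electrode_width = 0.42e-4 / fill, # wetted face area / fill level
    electrode_thickness = 1e-3,
    fill_level = fill,
    conductivity = 1.3,
    liquid_volume = vol,
    effective_liquid_area = vol / fill
  )
}

#' Fill level reached by a liquid volume
#'
#' @param volume Liquid volume in m^3 (>= 0).
#' @param area Effective horizontal liquid area in m^2 (> 0).
#' @return Fill level in m.
#' @export
fill_level_from_volume <- function(volume, area) {
  if (!is.finite(area) || area <= 0) {
    stop("invalid geometry: area must be positive", call. = FALSE)
  }
  if (!is.finite(volume) || volume < 0) {
    stop("invalid geometry: volume must be non-negative", call. = FALSE)
  }
  volume / area
}

#' Wetted area of one electrode face
#'
#' The liquid contacts each plate over its width times the fill level.
#'
#' @param geometry A `chamber_geometry` object.
#' @return Area in m^2.
#' @export
wetted_electrode_area <- function(geometry) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  geometry$electrode_width * geometry$fill_level
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat("Stimulation chamber (2D cross-section)\n")
  cat(sprintf("  well diameter      : %.2f mm\n", x$well_diameter * 1e3))
  cat(sprintf("  electrode gap      : %.2f mm\n", x$electrode_gap * 1e3))
  cat(sprintf("  electrode width    : %.2f mm\n", x$electrode_width * 1e3))
  cat(sprintf("  electrode thickness: %.2f mm\n", x$electrode_thickness * 1e3))
  cat(sprintf("  fill level         : %.2f mm\n", x$fill_level * 1e3))
  cat(sprintf("  conductivity       : %.3g S/m\n", x$conductivity))
  invisible(x)
}
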