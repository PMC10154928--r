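#' Morphological description of a flying animal
#'
#' Bundles the morphometric quantities the aerodynamic power models need.
#' Body frontal area may be supplied directly (e.g. measured from
#' photographs); when absent it is filled in from a mass allometry chosen by
#' the individual model.
#'
#' @param body_mass Body mass in kg.
#' @param wing_span Wing span in m (wingtip to wingtip, wings outstretched).
#' @param wing_area Combined area of both wings and the body section between
#'   them, in m^2.
#' @param wingbeat_freq Wingbeat frequency in Hz.
#' @param body_drag_coeff Dimensionless body drag coefficient referred to the
#'   body frontal area. Default 0.4, the value conventionally used for bat
#'   bodies.
#' @param body_frontal_area Optional body frontal area in m^2; `NULL` defers
#'   to the model's allometric default.
#'
#' @return An object of class `morphology`: a named list with the fields
#'   above plus derived `aspect_ratio` (span^2 / area).
#' @examples
#' bat <- morphology(body_mass = 0.0089, wing_span = 0.23,
#'                   wing_area = 0.0077, wingbeat_freq = 9.9)
#' bat$aspect_ratio
#' @export
morphology <- function(body_mass, wing_span, wing_area, wingbeat_freq,
                       body_drag_coeff = 0.4, body_frontal_area = NULL) {
  check_positive(body_mass, "body_mass")
  check_positive(wing_span, "wing_span")
  check_positive(wing_area, "wing_area")
  check_positive(wingbeat_freq, "wingbeat_freq")
  check_positive(body_drag_coeff, "body_drag_coeff")
  if (!is.null(body_frontal_area)) {
    check_positive(body_frontal_area, "body_frontal_area")
  }
  out <- list(
    body_mass = body_mass,
    wing_span = wing_span,
    wing_area = wing_area,
    wingbeat_freq = wingbeat_freq,
    body_drag_coeff = body_drag_coeff,
    body_frontal_area = body_frontal_area,
    aspect_ratio = wing_span^2 / wing_area
  )
  if (!is.finite(out$aspect_ratio)) {
    stop_invalid("aspect ratio is not finite; check wing_span and wing_area.")
  }
  structure(out, class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  cat("<morphology>\n")
  cat(sprintf("  body mass        %.4g kg\n", x$body_mass))
  cat(sprintf("  wing span        %.3g m\n", x$wing_span))
  cat(sprintf("  wing area        %.3g m^2\n", x$wing_area))
  cat(sprintf("  aspect ratio     %.3g\n", x$aspect_ratio))
  cat(sprintf("  wingbeat freq.   %.3g Hz\n", x$wingbeat_freq))
  cat(sprintf("  body drag coeff. %.3g\n", x$body_drag_coeff))
  if (!is.null(x$body_frontal_area)) {
    cat(sprintf("  frontal area     %.3g m^2 (supplied)\n", x$body_frontal_area))
  }
  invisible(x)
}

#' Morphology of the study bat
#'
#' Default morphometrics for a Nathusius' pipistrelle (*Pipistrellus
#' nathusii*): body mass 8.9 g, wing span 0.23 m, wing area 0.0077 m^2,
#' wingbeat frequency 9.9 Hz, body drag coefficient 0.4.
#'
#' @param ... Overrides passed on to [morphology()].
#' @return A `morphology` object.
#' @examples
#' pipistrelle_morphology()
#' @export
pipistrelle_morphology <- function(...) {
  defaults <- list(body_mass = 0.0089, wing_span = 0.23, wing_area = 0.0077,
                   wingbeat_freq = 9.9, body_drag_coeff = 0.4)
  do.call(morphology, modifyList(defaults, list(...)))
}

#' Ambient flight conditions
#'
#' @param air_density Air density in kg m^-3. Default 1.225 (sea-level
#'   standard atmosphere). Must lie in (0.8, 1.5).
#' @param gravity Gravitational acceleration in m s^-2.
#' @return An object of class `flight_conditions`.
#' @examples
#' flight_conditions()
#' @export
flight_conditions <- function(air_density = 1.225, gravity = 9.81) {
  check_positive(air_density, "air_density")
  check_positive(gravity, "gravity")
  if (air_density <= 0.8 || air_density >= 1.5) {
    stop_invalid("air_density %.3g kg m^-3 outside the plausible range (0.8, 1.5).",
                 air_density)
  }
  structure(list(air_density = air_density, gravity = gravity),
            class = "flight_conditions")
}

#' @export
print.flight_conditions <- function(x, ...) {
  cat(sprintf("<flight_conditions> rho = %.4g kg m^-3, g = %.4g m s^-2\n",
              x$air_density, x$gravity))
  invisible(x)
}

# Weight in newtons.
body_weight <- function(morph, conditions) morph$body_mass * conditions$gravity

# Body frontal area allometries (mass in kg, area in m^2).
frontal_area_allometry <- function(body_mass,
                                   which = c("hedenstrom_rosen", "pennycuick")) {
  which <- match.arg(which)
  switch(which,
    hedenstrom_rosen = 0.0129 * body_mass^0.614,
    pennycuick = 0.00813 * body_mass^0.666
  )
}

# Allometric basal metabolic rate (W), Pennycuick's passerine formula; used by
# the fuel-economy definition of maximum range speed.
bmr_allometric <- function(body_mass) 6.25 * body_mass^0.724
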