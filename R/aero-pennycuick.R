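#' Pennycuick-style fixed-wing power model
#'
#' Classic fixed-wing-theory decomposition of the mechanical power of steady
#' flapping flight into induced, parasite and profile components:
#' \deqn{P(U) = k \frac{W^2}{2 \rho U S_d} + \tfrac{1}{2}\rho U^3 S_b C_{db}
#'   + \frac{C_{pro}}{AR} P_{am}}
#' where \eqn{W} is weight, \eqn{S_d = \pi b^2/4} the wing disc area,
#' \eqn{S_b} the body frontal area, \eqn{AR} the aspect ratio and
#' \eqn{P_{am}} the absolute minimum of the induced-plus-parasite sum.
#' Induced power falls as \eqn{1/U}, parasite power rises as \eqn{U^3} and
#' profile power is a speed-independent constant.
#'
#' When `body_frontal_area` is not supplied in `morph` it is filled from a
#' mass allometry. The default, `"hedenstrom_rosen"`
#' (\eqn{S_b = 0.0129 M^{0.614}}), is the passerine frontal-area regression;
#' `"pennycuick"` (\eqn{S_b = 0.00813 M^{0.666}}) is the older waterfowl and
#' raptor regression.
#'
#' @param morph A [morphology()] object.
#' @param conditions A [flight_conditions()] object.
#' @param speed Air speed(s) in m s^-1; strictly positive.
#' @param induced_factor Induced power factor \eqn{k} (default 1.2).
#' @param profile_power_constant \eqn{C_{pro}} in the profile-power ratio
#'   \eqn{C_{pro}/AR} (default 8.4).
#' @param frontal_area Allometry used when the morphology has no measured
#'   frontal area; see Details.
#' @return A tibble with columns `speed`, `induced`, `parasite`, `profile`
#'   and `total` (all W). `total` is the exact sum of the three components.
#' @examples
#' pennycuick_power(pipistrelle_morphology(), flight_conditions(),
#'                  speed = c(4, 6, 8))
#' @seealso [pennycuick_model()] for a model object usable with
#'   [minimum_power_speed()] and [maximum_range_speed()].
#' @export
pennycuick_power <- function(morph, conditions = flight_conditions(), speed,
                             induced_factor = 1.2,
                             profile_power_constant = 8.4,
                             frontal_area = c("hedenstrom_rosen", "pennycuick")) {
  stopifnot(inherits(morph, "morphology"), inherits(conditions, "flight_conditions"))
  check_positive(speed, "speed")
  frontal_area <- match.arg(frontal_area)

  W <- body_weight(morph, conditions)
  rho <- conditions$air_density
  disc_area <- pi * morph$wing_span^2 / 4
  Sb <- morph$body_frontal_area %||%
    frontal_area_allometry(morph$body_mass, frontal_area)

  A <- induced_factor * W^2 / (2 * rho * disc_area) # induced = A / U
  B <- 0.5 * rho * Sb * morph$body_drag_coeff       # parasite = B * U^3

  # Absolute minimum of induced + parasite fixes the constant profile power.
  u_am <- (A / (3 * B))^0.25
  p_am <- A / u_am + B * u_am^3
  profile <- (profile_power_constant / morph$aspect_ratio) * p_am

  induced <- A / speed
  parasite <- B * speed^3
  tibble(
    speed = speed,
    induced = induced,
    parasite = parasite,
    profile = rep(profile, length(speed)),
    total = induced + parasite + profile
  )
}

#' Pennycuick-style model object
#'
#' Wraps [pennycuick_power()] into a reusable model for characteristic-speed
#' solvers. Its maximum-range speed follows the fuel-economy convention:
#' the tangent from the origin to the *chemical* power curve
#' \eqn{P_{chem}(U) = 1.1\,(P_{mech}(U)/\eta + BMR)}, with conversion
#' efficiency `efficiency` and a basal metabolic rate defaulting to the
#' passerine allometry \eqn{6.25\,M^{0.724}} W. Set `range_basis =
#' "mechanical"` for the tangent to the mechanical curve instead.
#'
#' @inheritParams pennycuick_power
#' @param efficiency Whole-animal conversion efficiency used in the chemical
#'   power curve (default 0.23).
#' @param respiration_factor Respiratory/circulatory overhead factor
#'   (default 1.1).
#' @param bmr Basal metabolic rate in W; `NULL` uses the allometric default.
#' @param range_basis Power curve on which the maximum-range tangent is
#'   taken: `"chemical"` (default) or `"mechanical"`.
#' @return An object of class `c("pennycuick_model", "flight_power_model")`.
#' @examples
#' mod <- pennycuick_model(pipistrelle_morphology())
#' minimum_power_speed(mod)
#' maximum_range_speed(mod)
#' @export
pennycuick_model <- function(morph, conditions = flight_conditions(),
                             induced_factor = 1.2,
                             profile_power_constant = 8.4,
                             frontal_area = c("hedenstrom_rosen", "pennycuick"),
                             efficiency = 0.23, respiration_factor = 1.1,
                             bmr = NULL,
                             range_basis = c("chemical", "mechanical")) {
  frontal_area <- match.arg(frontal_area)
  range_basis <- match.arg(range_basis)
  check_positive(efficiency, "efficiency")
  bmr <- bmr %||% bmr_allometric(morph$body_mass)
  structure(
    list(morph = morph, conditions = conditions,
         induced_factor = induced_factor,
         profile_power_constant = profile_power_constant,
         frontal_area = frontal_area,
         efficiency = efficiency, respiration_factor = respiration_factor,
         bmr = bmr, range_basis = range_basis,
         label = "Pennycuick fixed-wing model"),
    class = c("pennycuick_model", "flight_power_model")
  )
}

#' @export
predict.pennycuick_model <- function(object, speed, ...) {
  pennycuick_power(object$morph, object$conditions, speed,
                   induced_factor = object$induced_factor,
                   profile_power_constant = object$profile_power_constant,
                   frontal_area = object$frontal_area)
}

#' @export
print.flight_power_model <- function(x, ...) {
  cat(sprintf("<%s>\n", x$label))
  cat(sprintf("  mass %.4g kg, span %.3g m, area %.3g m^2, f %.3g Hz\n",
              x$morph$body_mass, x$morph$wing_span, x$morph$wing_area,
              x$morph$wingbeat_freq))
  cat(sprintf("  U_mp = %.1f m/s, U_mr = %.1f m/s\n",
              minimum_power_speed(x), maximum_range_speed(x)))
  invisible(x)
}

# Total mechanical power as a function of speed, vectorized.
total_power_fun <- function(model) {
  function(U) predict(model, U)$total
}
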