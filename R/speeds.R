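#' Cubic-plus-inverse power curve
#'
#' The U-shaped flight power curve family
#' \deqn{P(U) = k_1 U^3 + k_2 / U + k_3,}
#' whose three coefficients correspond to parasite, induced and profile
#' power. Its minimum-power speed has the closed form
#' \eqn{U_{mp} = (k_2 / 3 k_1)^{1/4}}.
#'
#' @param k1 Coefficient of \eqn{U^3} (W s^3 m^-3); must be positive.
#' @param k2 Coefficient of \eqn{1/U} (W m s^-1); must be positive.
#' @param k3 Constant term (W); non-negative.
#' @return An object of class `power_curve`.
#' @examples
#' pc <- power_curve(3.73e-4, 2.52, 0.490)
#' minimum_power_speed(pc)
#' predict(pc, 5:9)
#' @export
power_curve <- function(k1, k2, k3 = 0) {
  check_positive(k1, "k1")
  check_positive(k2, "k2")
  if (!is.numeric(k3) || length(k3) != 1 || is.na(k3)) {
    stop_invalid("`k3` must be a single number.")
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3), class = "power_curve")
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("<power_curve> P(U) = %.4g U^3 + %.4g / U + %.4g\n",
              x$k1, x$k2, x$k3))
  invisible(x)
}

#' @export
predict.power_curve <- function(object, speed, ...) {
  check_positive(speed, "speed")
  object$k1 * speed^3 + object$k2 / speed + object$k3
}

as_power_function <- function(x) {
  if (inherits(x, "power_curve")) return(function(U) predict(x, U))
  if (inherits(x, "power_curve_fit")) return(function(U) predict(x, U))
  if (inherits(x, "flight_power_model")) return(total_power_fun(x))
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 3) {
    pc <- power_curve(x[[1]], x[[2]], x[[3]])
    return(function(U) predict(pc, U))
  }
  stop_invalid("cannot interpret `x` as a power curve, model or function.")
}

#' Minimum power speed
#'
#' Speed at which flight power is lowest. For a [power_curve()] (or a fitted
#' [fit_power_curve()] object) the analytic solution
#' \eqn{(k_2/3k_1)^{1/4}} is used; for functions and aerodynamic model
#' objects the total power is minimized numerically on `interval` to within
#' about 1e-3 m s^-1.
#'
#' @param x A `power_curve`, `power_curve_fit`, flight-power model object
#'   ([pennycuick_model()], [flap_model()]), a numeric coefficient triple,
#'   or a function of speed.
#' @param interval Bracketing interval (m s^-1) for numerical minimization.
#' @param ... Unused.
#' @return Minimum power speed in m s^-1.
#' @examples
#' minimum_power_speed(power_curve(3.73e-4, 2.52, 0.490)) # 6.9 m/s
#' @export
minimum_power_speed <- function(x, ...) UseMethod("minimum_power_speed")

#' @rdname minimum_power_speed
#' @export
minimum_power_speed.power_curve <- function(x, ...) {
  (x$k2 / (3 * x$k1))^0.25
}

#' @rdname minimum_power_speed
#' @export
minimum_power_speed.default <- function(x, interval = c(0.5, 30), ...) {
  if (is.numeric(x) && length(x) == 3) {
    return(minimum_power_speed(power_curve(x[[1]], x[[2]], x[[3]])))
  }
  f <- as_power_function(x)
  opt <- optimize(f, interval, tol = 1e-8)
  check_interior_minimum(f, opt$minimum, interval, what = "power")
  opt$minimum
}

#' Maximum range speed
#'
#' Speed minimizing the cost of transport, i.e. where the tangent from the
#' origin touches the power curve. For aerodynamic model objects the curve
#' follows the model's own range convention (`range_basis`): the
#' Pennycuick-style model uses its chemical power curve (fuel economy), the
#' flapping model its mechanical curve; `basis` overrides this.
#'
#' @inheritParams minimum_power_speed
#' @param basis For flight-power models: `"chemical"` or `"mechanical"`;
#'   `NULL` defers to the model's convention.
#' @return Maximum range speed in m s^-1 (always at or above the
#'   minimum-power speed of the same curve).
#' @examples
#' maximum_range_speed(power_curve(9.21e-5, 0.176, 0.0297))
#' @export
maximum_range_speed <- function(x, ...) UseMethod("maximum_range_speed")

#' @rdname maximum_range_speed
#' @export
maximum_range_speed.flight_power_model <- function(x, interval = c(0.5, 30),
                                                   basis = NULL, ...) {
  basis <- basis %||% x$range_basis
  p <- total_power_fun(x)
  f <- if (identical(basis, "chemical")) {
    # tangent to 1.1 (P/eta + BMR) is the tangent to P + eta * BMR
    eta <- x$efficiency %||% 0.23
    bmr <- x$bmr %||% bmr_allometric(x$morph$body_mass)
    function(U) (p(U) + eta * bmr) / U
  } else {
    function(U) p(U) / U
  }
  opt <- optimize(f, interval, tol = 1e-8)
  check_interior_minimum(f, opt$minimum, interval, what = "cost of transport")
  opt$minimum
}

#' @rdname maximum_range_speed
#' @export
maximum_range_speed.default <- function(x, interval = c(0.5, 30), ...) {
  f <- as_power_function(x)
  g <- function(U) f(U) / U
  opt <- optimize(g, interval, tol = 1e-8)
  check_interior_minimum(g, opt$minimum, interval, what = "cost of transport")
  opt$minimum
}

check_interior_minimum <- function(f, u, interval, what) {
  tol <- 1e-3
  if (u - interval[1] < 10 * tol || interval[2] - u < 10 * tol) {
    stop_numeric("no interior %s minimum on [%.3g, %.3g]; the curve may be monotone.",
                 what, interval[1], interval[2])
  }
  invisible(u)
}

#' Characteristic speeds of a power curve or model
#'
#' @inheritParams minimum_power_speed
#' @return A one-row tibble with `u_mp` and `u_mr` (m s^-1).
#' @examples
#' characteristic_speeds(power_curve(3.73e-4, 2.52, 0.490))
#' @export
characteristic_speeds <- function(x, ...) {
  u_mp <- minimum_power_speed(x, ...)
  u_mr <- maximum_range_speed(x, ...)
  tibble(u_mp = u_mp, u_mr = u_mr)
}

#' Predict metabolic power from mechanical power
#'
#' The conventional conversion from mechanical to metabolic flight power,
#' \deqn{P_{met} = 1.1\,(P_{mech}/\eta + BMR),}
#' assuming conversion efficiency \eqn{\eta} (classically 23%) and a 1.1
#' respiratory/circulatory overhead.
#'
#' @param p_mech Mechanical power in W (non-negative).
#' @param bmr Basal metabolic rate in W (non-negative).
#' @param efficiency Conversion efficiency in (0, 1].
#' @param overhead Respiratory/circulatory overhead factor.
#' @return Metabolic power in W.
#' @examples
#' predict_met_from_mech(0.092, 0.08, 0.23) # 0.528 W
#' @export
predict_met_from_mech <- function(p_mech, bmr, efficiency = 0.23,
                                  overhead = 1.1) {
  check_positive(p_mech, "p_mech", allow_zero = TRUE)
  check_positive(bmr, "bmr", allow_zero = TRUE)
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    stop_invalid("`efficiency` must lie in (0, 1].")
  }
  overhead * (p_mech / efficiency + bmr)
}

#' Invert the metabolic power prediction for efficiency
#'
#' Algebraic inverse of [predict_met_from_mech()]:
#' \eqn{\eta = 1.1\,P_{mech} / (P_{met} - 1.1\,BMR)}.
#'
#' @param p_met Metabolic power in W.
#' @inheritParams predict_met_from_mech
#' @return Implied conversion efficiency (fraction).
#' @examples
#' efficiency_from_powers(predict_met_from_mech(0.09, 0.08, 0.23), 0.09, 0.08)
#' @export
efficiency_from_powers <- function(p_met, p_mech, bmr, overhead = 1.1) {
  denom <- p_met - overhead * bmr
  if (any(denom <= 0)) {
    stop_invalid("p_met must exceed the overhead-scaled BMR.")
  }
  overhead * p_mech / denom
}
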