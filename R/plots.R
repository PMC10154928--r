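# ggplot2 presentation layer.

#' Plot the component decomposition of an aerodynamic power model
#'
#' @param model A [pennycuick_model()] or [flap_model()].
#' @param speeds Speed grid in m s^-1.
#' @return A ggplot.
#' @examples
#' plot_power_components(pennycuick_model(pipistrelle_morphology()))
#' @export
plot_power_components <- function(model, speeds = seq(2, 12, by = 0.1)) {
  stopifnot(inherits(model, "flight_power_model"))
  d <- predict(model, speeds) %>%
    select("speed", "induced", "parasite", "profile", "total") %>%
    tidyr::pivot_longer(-"speed", names_to = "component",
                        values_to = "power")
  ggplot2::ggplot(d, ggplot2::aes(.data$speed, .data$power,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "air speed (m/s)", y = "mechanical power (W)",
                  title = model$label) +
    ggplot2::theme_minimal()
}

#' @method autoplot power_curve_fit
#' @export
autoplot.power_curve_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$speed, .data$power)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$individual)),
                        alpha = 0.8) +
    ggplot2::labs(x = "air speed (m/s)", y = "power (W)",
                  colour = "individual") +
    ggplot2::theme_minimal()
  if (!is.null(object$curve)) {
    grid <- seq(min(d$speed), max(d$speed), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(speed = grid, power = predict(object, grid)),
      linewidth = 0.8)
  }
  p
}

#' @method autoplot efficiency_pairs
#' @export
autoplot.efficiency_pairs <- function(object, ...) {
  if (nrow(object$pairs) == 0) {
    abort("no pairs to plot.", class = "flightpower_data_error")
  }
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$speed, 100 * .data$efficiency)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$individual)),
                        alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::labs(x = "air speed (m/s)", y = "conversion efficiency (%)",
                  colour = "individual") +
    ggplot2::theme_minimal()
}

#' @method autoplot efficiency_scaling
#' @export
autoplot.efficiency_scaling <- function(object, ...) {
  d <- object$data %>%
    group_by(.data$species, .data$taxon) %>%
    summarise(log_mass = .data$log_mass[1],
              log_eta = mean(.data$log_eta), .groups = "drop")
  grid <- tibble(log_mass = seq(min(d$log_mass), max(d$log_mass),
                                length.out = 100))
  grid$log_eta <- object$intercept + object$slope * grid$log_mass
  ggplot2::ggplot(d, ggplot2::aes(.data$log_mass, .data$log_eta)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$taxon), size = 2) +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "log10 body mass (g)",
                  y = "log10 conversion efficiency (%)",
                  shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the streamwise vorticity of a wake frame
#'
#' @param ws A [wake_series()].
#' @param frame Frame index.
#' @return A ggplot raster of \eqn{\omega_x}.
#' @examples
#' plot_wake_vorticity(simulate_vortex_wake(seed = 1))
#' @export
plot_wake_vorticity <- function(ws, frame = 1) {
  om <- streamwise_vorticity(ws, frame)
  d <- tibble(
    y = rep(ws$y, times = length(ws$z)),
    z = rep(ws$z, each = length(ws$y)),
    omega = as.vector(om)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$y, .data$z, fill = .data$omega)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "y (m)", y = "z (m)", fill = "omega_x (1/s)") +
    ggplot2::theme_minimal()
}
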