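# Metabolic power from 13C-labelled sodium bicarbonate washout.
#
# Model: a single well-mixed body bicarbonate pool of size `pool_ml`
# (ml CO2 equivalent). After the labelled dose equilibrates to enrichment
# E0, CO2 production at rate R(t) (ml min^-1) washes the label out:
#   E(t) = E0 * exp(-(1/pool) * integral R dt),
# so enrichment decays exponentially at rate k = R/pool while R is constant,
# and a flight (elevated R) steepens the decay. Comparing the pre- and
# post-flight washout exponentials yields the extra CO2 produced in flight.

#' Flight event timing
#'
#' @param start,end Flight-trial start and end times in s (trace time base).
#' @param landings Optional two-column data frame (`start`, `end`) of landing
#'   intervals nested within the trial, during which the animal was not
#'   airborne.
#' @return An object of class `flight_event` with derived `flight_fraction`,
#'   the airborne share of the trial.
#' @examples
#' flight_event(300, 366, landings = data.frame(start = 320, end = 326))
#' @export
flight_event <- function(start, end, landings = NULL) {
  if (end <= start) stop_invalid("`end` must exceed `start`.")
  if (is.null(landings)) {
    landings <- tibble(start = numeric(0), end = numeric(0))
  }
  landings <- as_tibble(landings)
  check_columns(landings, c("start", "end"), "landings")
  if (nrow(landings) > 0 &&
      (any(landings$start < start) || any(landings$end > end) ||
       any(landings$end <= landings$start))) {
    stop_invalid("landing intervals must be nested within [start, end].")
  }
  landed <- sum(landings$end - landings$start)
  ff <- 1 - landed / (end - start)
  structure(list(start = start, end = end, landings = landings,
                 flight_fraction = ff),
            class = "flight_event")
}

#' @export
print.flight_event <- function(x, ...) {
  cat(sprintf("<flight_event> %.1f-%.1f s, %d landing(s), airborne %.0f%%\n",
              x$start, x$end, nrow(x$landings), 100 * x$flight_fraction))
  invisible(x)
}

#' Fit an exponential washout to a breath-trace phase
#'
#' Nonlinear least-squares fit of \eqn{E(t) = baseline + A e^{-k t}} to the
#' isotope enrichment of one washout phase.
#'
#' @param trace A breath-trace tibble with columns `time_s`,
#'   `enrichment_ape` and `phase`.
#' @param phase Phase label to fit, typically `"washout_pre"` or
#'   `"washout_post"`.
#' @param fit_baseline Estimate the baseline enrichment (default `FALSE`:
#'   pinned to 0, appropriate after baseline subtraction).
#' @return An object of class `washout_fit`: list with `amplitude`,
#'   `decay_rate` (s^-1), `baseline`, `sigma` (residual sd), `n`, and the
#'   fitted time origin. Errors (class `flightpower_fit_error`) when the
#'   trace does not decay.
#' @examples
#' sim <- simulate_washout_trace(seed = 1)
#' fit_washout(sim$trace, "washout_pre")
#' @export
fit_washout <- function(trace, phase = "washout_pre", fit_baseline = FALSE) {
  check_columns(trace, c("time_s", "enrichment_ape", "phase"), "breath trace")
  d <- trace %>%
    filter(.data$phase == !!phase, is.finite(.data$enrichment_ape))
  if (nrow(d) < 10) {
    stop_data("phase '%s' has %d usable samples; need at least 10.",
              phase, nrow(d))
  }
  tt <- d$time_s
  ee <- d$enrichment_ape
  if (max(ee) - min(ee) < .Machine$double.eps^0.5 * max(abs(ee), 1)) {
    abort(sprintf("phase '%s' enrichment is constant; no washout to fit.",
                  phase), class = "flightpower_fit_error")
  }
  # log-linear start values on baseline-0 assumption
  pos <- ee > 0
  slope0 <- if (sum(pos) >= 2) {
    -coef(lm(log(ee[pos]) ~ tt[pos]))[[2]]
  } else {
    1e-3
  }
  start <- list(A = max(ee), k = max(slope0, 1e-6))
  fit <- tryCatch({
    if (fit_baseline) {
      minpack.lm::nlsLM(ee ~ b + A * exp(-k * (tt - min(tt))),
                        start = c(start, list(b = min(ee))),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(ee ~ A * exp(-k * (tt - min(tt))),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    abort(sprintf("washout fit failed for phase '%s': %s", phase,
                  conditionMessage(e)), class = "flightpower_fit_error")
  })
  cf <- coef(fit)
  k <- unname(cf["k"])
  if (!is.finite(k) || k <= 0) {
    abort(sprintf("phase '%s' does not decay (k = %.3g); flight excluded.",
                  phase, k), class = "flightpower_fit_error")
  }
  structure(
    list(amplitude = unname(cf["A"]), decay_rate = k,
         baseline = if (fit_baseline) unname(cf["b"]) else 0,
         t0 = min(tt), sigma = sd(resid(fit)), n = nrow(d), phase = phase),
    class = "washout_fit"
  )
}

#' @export
print.washout_fit <- function(x, ...) {
  cat(sprintf("<washout_fit> %s: E = %.3g + %.3g exp(-%.4g t), n = %d\n",
              x$phase, x$baseline, x$amplitude, x$decay_rate, x$n))
  invisible(x)
}

#' @method tidy washout_fit
#' @export
tidy.washout_fit <- function(x, ...) {
  tibble(term = c("amplitude", "decay_rate", "baseline"),
         estimate = c(x$amplitude, x$decay_rate, x$baseline))
}

# log-enrichment of a fitted washout extrapolated to absolute time t
log_enrichment_at <- function(fit, t) {
  log(fit$amplitude) - fit$decay_rate * (t - fit$t0)
}

#' CO2 production rate of a flight from washout kinetics
#'
#' Isotope-dilution estimate of the whole-flight CO2 production rate. The
#' resting rate is the mean pre/post decay rate times the bicarbonate pool;
#' the extra label washed out by the flight is the gap between the pre- and
#' post-flight washout lines (in log enrichment) at the flight midpoint, and
#' is attributed to a contiguous airborne interval of length
#' `flight_fraction * (end - start)` centred on the midpoint.
#'
#' @inheritParams fit_washout
#' @param event A [flight_event()].
#' @param pool_ml Bicarbonate pool size in ml CO2 equivalent. Defaults to
#'   the `pool_ml` attribute of `trace` when present (synthetic traces carry
#'   it); otherwise required — for real data it is a calibration constant
#'   derived from the administered dose and equilibrium enrichment.
#' @param pre_fit,post_fit Optional [fit_washout()] results (computed when
#'   `NULL`).
#' @param consistency_tol Maximal allowed relative disagreement between pre-
#'   and post-flight decay rates before an instability error is raised.
#' @return A one-row tibble with `vco2_flight`, `vco2_rest` (ml min^-1),
#'   `excess_ml` (extra CO2 volume attributed to flight), and
#'   `flight_fraction`.
#' @examples
#' sim <- simulate_washout_trace(seed = 1)
#' flight_vco2(sim$trace, sim$event)
#' @export
flight_vco2 <- function(trace, event, pool_ml = NULL,
                        pre_fit = NULL, post_fit = NULL,
                        consistency_tol = 0.5) {
  stopifnot(inherits(event, "flight_event"))
  pool_ml <- pool_ml %||% attr(trace, "pool_ml")
  if (is.null(pool_ml)) {
    stop_invalid("`pool_ml` is required (no pool attribute on the trace).")
  }
  check_positive(pool_ml, "pool_ml")
  pre_fit <- pre_fit %||% fit_washout(trace, "washout_pre")
  post_fit <- post_fit %||% fit_washout(trace, "washout_post")
  k_pre <- pre_fit$decay_rate
  k_post <- post_fit$decay_rate
  if (abs(k_pre - k_post) > consistency_tol * mean(c(k_pre, k_post))) {
    stop_numeric("pre/post washout rates disagree (%.3g vs %.3g s^-1).",
                 k_pre, k_post)
  }
  k_rest <- mean(c(k_pre, k_post))          # s^-1
  vco2_rest <- k_rest * 60 * pool_ml        # ml min^-1
  t_air_min <- event$flight_fraction * (event$end - event$start) / 60
  if (t_air_min <= 0) {
    return(tibble(vco2_flight = vco2_rest, vco2_rest = vco2_rest,
                  excess_ml = 0, flight_fraction = 0))
  }
  t_mid <- (event$start + event$end) / 2
  # label deficit: pre line minus post line at the midpoint (in log E)
  gap <- log_enrichment_at(pre_fit, t_mid) - log_enrichment_at(post_fit, t_mid)
  # gap = (integral of R dt - R_rest dt) / pool over the flight window
  excess_ml <- gap * pool_ml
  vco2_flight <- vco2_rest + excess_ml / t_air_min
  tibble(vco2_flight = vco2_flight, vco2_rest = vco2_rest,
         excess_ml = excess_ml, flight_fraction = event$flight_fraction)
}

#' Fuel model: energy yield per ml of CO2
#'
#' @param name `"glycogen"` (21.1 J ml^-1 CO2; carbohydrate oxidation, the
#'   default for short bat flights) or `"mixed"` (23.7 J ml^-1 CO2; 80%
#'   carbohydrate / 20% lipid, respiratory quotient 0.88).
#' @return A list with `name` and `joules_per_ml_co2`.
#' @examples
#' fuel_model("glycogen")$joules_per_ml_co2
#' @export
fuel_model <- function(name = c("glycogen", "mixed")) {
  name <- match.arg(name)
  structure(list(name = name,
                 joules_per_ml_co2 = c(glycogen = 21.1, mixed = 23.7)[[name]]),
            class = "fuel_model")
}

#' Metabolic power from CO2 production
#'
#' \eqn{P = \dot V_{CO2} / 60 \times} energy equivalent (J ml^-1).
#'
#' @param vco2 CO2 production in ml min^-1 (non-negative).
#' @param fuel A [fuel_model()] (or its name).
#' @return Power in W.
#' @examples
#' power_from_vco2(2.84, fuel_model("glycogen")) # ~1 W
#' @export
power_from_vco2 <- function(vco2, fuel = fuel_model("glycogen")) {
  check_positive(vco2, "vco2", allow_zero = TRUE)
  if (is.character(fuel)) fuel <- fuel_model(fuel)
  vco2 / 60 * fuel$joules_per_ml_co2
}

#' Basal metabolic rate from resting respirometry
#'
#' Converts resting gas exchange to W. Oxygen consumption uses the oxyjoule
#' equivalent 20.1 J ml^-1 O2; CO2 production uses the glycogen factor
#' 21.1 J ml^-1 unless another energy equivalent is supplied.
#'
#' @param rate Gas exchange rate in ml min^-1.
#' @param mode `"vo2"` or `"vco2"`.
#' @param temperature_c Optional chamber temperature; a warning is issued
#'   outside the 28-35 C thermoneutral zone.
#' @param joules_per_ml Override of the energy equivalent.
#' @return Power in W.
#' @examples
#' bmr_from_respirometry(0.239) # ~0.080 W
#' @export
bmr_from_respirometry <- function(rate, mode = c("vo2", "vco2"),
                                  temperature_c = NULL,
                                  joules_per_ml = NULL) {
  mode <- match.arg(mode)
  check_positive(rate, "rate", allow_zero = TRUE)
  if (!is.null(temperature_c) &&
      (temperature_c < 28 || temperature_c > 35)) {
    warn(sprintf("chamber temperature %.1f C outside thermoneutrality (28-35 C)",
                 temperature_c))
  }
  jm <- joules_per_ml %||% switch(mode, vo2 = 20.1, vco2 = 21.1)
  rate / 60 * jm
}

#' Filter flight metabolic estimates
#'
#' Applies the study's selection rules in order: (1) drop flights with less
#' than 60% of the trial airborne; (2) within speed groups (speeds rounded
#' to the nearest `bin_width`), drop outliers whose Z-score (mean-centred,
#' population-sd-scaled) strictly exceeds `z_max`; (3) drop individuals
#' left with fewer than `min_flights` flights. Groups of size one have an
#' undefined Z-score and are retained.
#'
#' @param results Tibble with columns `individual`, `speed`, `p_met` and
#'   `flight_fraction`.
#' @param fraction_min Minimum airborne fraction (default 0.6).
#' @param z_max Z-score threshold (default 2; strictly exceeding values are
#'   dropped).
#' @param min_flights Minimum surviving flights per individual ("more than
#'   three" reads as >= 4).
#' @param bin_width Speed-group width in m s^-1.
#' @return The retained rows, with a `z_score` column; a `drop_log`
#'   attribute records each dropped flight and the rule that removed it.
#' @examples
#' recs <- tibble::tibble(individual = rep("a", 5), speed = rep(6, 5),
#'                        p_met = c(1, 1, 1, 1, 3),
#'                        flight_fraction = rep(0.9, 5))
#' filter_flights(recs)
#' @export
filter_flights <- function(results, fraction_min = 0.6, z_max = 2,
                           min_flights = 4, bin_width = 1) {
  check_columns(results, c("individual", "speed", "p_met", "flight_fraction"),
                "metabolic results")
  d <- results %>% mutate(.flight = row_number())
  drops <- list()

  keep_fraction <- d %>% filter(.data$flight_fraction >= fraction_min)
  drops$fraction <- d %>%
    filter(.data$flight_fraction < fraction_min) %>%
    mutate(reason = sprintf("airborne fraction %.2f < %.2f",
                            .data$flight_fraction, fraction_min))

  z_scored <- keep_fraction %>%
    group_by(speed_group = round_to(.data$speed, bin_width)) %>%
    mutate(z_score = if (n() > 1 && pop_sd(.data$p_met) > 0) {
      (.data$p_met - mean(.data$p_met)) / pop_sd(.data$p_met)
    } else {
      0 # singleton or constant group: Z undefined, flights retained
    }) %>%
    ungroup()
  keep_z <- z_scored %>% filter(abs(.data$z_score) <= z_max)
  drops$z <- z_scored %>%
    filter(abs(.data$z_score) > z_max) %>%
    mutate(reason = sprintf("outlier |Z| = %.2f > %g at %g m/s",
                            abs(.data$z_score), z_max, .data$speed_group))

  counts <- keep_z %>% group_by(.data$individual) %>%
    mutate(.n_flights = n()) %>% ungroup()
  keep_ind <- counts %>% filter(.data$.n_flights >= min_flights)
  drops$individual <- counts %>%
    filter(.data$.n_flights < min_flights) %>%
    mutate(reason = sprintf("individual has %d flights (< %d)",
                            .data$.n_flights, min_flights))

  out <- keep_ind %>% select(-".n_flights", -"speed_group")
  log <- bind_rows(drops) %>%
    select(".flight", "individual", "speed", "reason")
  attr(out, "drop_log") <- log
  out %>% select(-".flight")
}
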