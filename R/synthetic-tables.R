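# Synthetic breath traces, flight power records and species tables with
# ground-truth sidecars.

#' Simulate a bicarbonate washout breath trace with a flight
#'
#' Forward model of the labelled-bicarbonate experiment: a single
#' well-mixed bicarbonate pool of `pool_ml` ml CO2 equivalent is enriched
#' to `e0` atom-percent excess, then washes out exponentially at rate
#' \eqn{k = \dot V_{CO2}/pool}. During the airborne portions of the flight
#' trial CO2 production steps from `resting_vco2` to `flight_vco2`,
#' steepening the washout. Enrichment is unobserved while the animal is in
#' the wind tunnel (the flight phase rows carry `NA`). Defaults mimic the
#' study protocol: ~1 min flights, washout monitored for 15 min after.
#'
#' @param resting_vco2 Resting CO2 production in ml min^-1.
#' @param flight_vco2 CO2 production while airborne in ml min^-1.
#' @param pool_ml Bicarbonate pool in ml CO2 equivalent.
#' @param e0 Enrichment at the start of washout (atom-percent excess).
#' @param washout_pre_duration,flight_duration,washout_post_duration Phase
#'   durations in s.
#' @param baseline_duration,equilibration_duration Durations of the
#'   pre-dose baseline and post-dose equilibration phases in s.
#' @param landings Optional data frame (`start`, `end`, in s relative to
#'   flight start) of landing intervals during the trial.
#' @param noise_sd Multiplicative enrichment noise sd (fraction).
#' @param sample_dt Sampling interval in s.
#' @param seed Optional RNG seed.
#' @return A list with `trace` (tibble: `time_s`, `enrichment_ape`,
#'   `co2_ml_min`, `phase`; carries the pool as an attribute), `event`
#'   (a [flight_event()]) and `truth` (all generating rates).
#' @examples
#' sim <- simulate_washout_trace(seed = 1)
#' flight_vco2(sim$trace, sim$event)
#' @export
simulate_washout_trace <- function(resting_vco2 = 0.5, flight_vco2 = 2.84,
                                   pool_ml = 2.0, e0 = 20,
                                   washout_pre_duration = 300,
                                   flight_duration = 66,
                                   washout_post_duration = 900,
                                   baseline_duration = 120,
                                   equilibration_duration = 180,
                                   landings = NULL,
                                   noise_sd = 0, sample_dt = 1,
                                   seed = NULL) {
  check_positive(resting_vco2, "resting_vco2")
  check_positive(flight_vco2, "flight_vco2")
  check_positive(pool_ml, "pool_ml")

  t_wash0 <- baseline_duration + equilibration_duration
  fl_start <- t_wash0 + washout_pre_duration
  fl_end <- fl_start + flight_duration
  t_end <- fl_end + washout_post_duration
  time_s <- seq(0, t_end, by = sample_dt)

  landings_abs <- if (is.null(landings)) {
    tibble(start = numeric(0), end = numeric(0))
  } else {
    as_tibble(landings) %>%
      mutate(start = .data$start + fl_start, end = .data$end + fl_start)
  }
  event <- flight_event(fl_start, fl_end, landings_abs)

  airborne_at <- function(t) {
    inflight <- t >= fl_start & t < fl_end
    if (nrow(landings_abs) > 0) {
      for (i in seq_len(nrow(landings_abs))) {
        inflight <- inflight &
          !(t >= landings_abs$start[i] & t < landings_abs$end[i])
      }
    }
    inflight
  }
  vco2_at <- function(t) ifelse(airborne_at(t), flight_vco2, resting_vco2)

  phase <- cut(time_s,
               breaks = c(-Inf, baseline_duration, t_wash0, fl_start, fl_end,
                          Inf),
               labels = c("baseline", "equilibration", "washout_pre",
                          "flight", "washout_post"), right = FALSE)
  phase <- as.character(phase)

  # cumulative label washout from t_wash0 (rates are per minute)
  co2 <- vco2_at(time_s)
  washed <- cumsum(c(0, (co2[-1] + co2[-length(co2)]) / 2 *
                       diff(time_s) / 60)) # trapezoid, ml
  washed0 <- washed[which.min(abs(time_s - t_wash0))]
  enrichment <- rep(NA_real_, length(time_s))
  pre_dose <- phase == "baseline"
  equil <- phase == "equilibration"
  washing <- time_s >= t_wash0
  enrichment[pre_dose] <- 0
  enrichment[equil] <- e0 * (1 - exp(-5 * (time_s[equil] - baseline_duration) /
                                       equilibration_duration))
  enrichment[washing] <- e0 * exp(-(washed[washing] - washed0) / pool_ml)

  with_local_seed(seed, {
    if (noise_sd > 0) {
      enrichment <- enrichment * (1 + rnorm(length(enrichment), sd = noise_sd))
    }
  })
  enrichment[phase == "flight"] <- NA_real_ # animal off the analyzer
  co2[phase == "flight"] <- NA_real_

  trace <- tibble(time_s = time_s, enrichment_ape = enrichment,
                  co2_ml_min = co2, phase = phase)
  attr(trace, "pool_ml") <- pool_ml
  truth <- list(resting_vco2 = resting_vco2, flight_vco2 = flight_vco2,
                pool_ml = pool_ml, e0 = e0,
                decay_rate_rest = resting_vco2 / pool_ml / 60, # s^-1
                flight_fraction = event$flight_fraction,
                noise_sd = noise_sd, seed = seed)
  list(trace = trace, event = event, truth = truth)
}

#' Simulate per-flight power records with individual effects
#'
#' Draws flight power observations from the cubic-plus-inverse curve
#' \eqn{P = k_1 U^3 + k_2/U + k_3} plus a Gaussian random intercept per
#' individual and Gaussian residual noise. Defaults mimic the study's
#' metabolic data: eight ~8.9 g bats flying between 4 and 9 m s^-1 on the
#' published metabolic curve. For mechanical-style records pass the
#' mechanical coefficients and smaller noise.
#'
#' @param k1,k2,k3 True curve coefficients (defaults: the published
#'   metabolic power curve).
#' @param n_individuals,flights_per_individual Design size.
#' @param speed_range Speed range in m s^-1; flight speeds are uniform
#'   within it.
#' @param noise_sd Residual sd in W.
#' @param ranef_sd Individual random-intercept sd in W.
#' @param mass_mean_kg,mass_cv Body-mass distribution of individuals
#'   (lognormal-free: normal truncated at 60% of the mean).
#' @param power_type `"met"` or `"mech"`; mechanical records also carry a
#'   `lift` column equal to body weight.
#' @param gravity m s^-2 (weight conversion).
#' @param seed Optional RNG seed.
#' @return A tibble (`individual`, `speed`, `power`, `power_type`,
#'   `mass_kg`, `body_weight`, `lift`) with a `truth` attribute (true
#'   coefficients, per-individual intercepts and masses).
#' @examples
#' recs <- simulate_power_records(seed = 1)
#' fit_power_curve(recs, u_mp_prior = 6.9)
#' @export
simulate_power_records <- function(k1 = 3.73e-4, k2 = 2.52, k3 = 0.490,
                                   n_individuals = 8,
                                   flights_per_individual = 6,
                                   speed_range = c(4, 9),
                                   noise_sd = 0.1, ranef_sd = 0.05,
                                   mass_mean_kg = 0.0089, mass_cv = 0.1,
                                   power_type = c("met", "mech"),
                                   gravity = 9.81, seed = NULL) {
  power_type <- match.arg(power_type)
  check_positive(speed_range, "speed_range")
  with_local_seed(seed, {
    ids <- sprintf("bat%02d", seq_len(n_individuals))
    masses <- pmax(rnorm(n_individuals, mass_mean_kg, mass_cv * mass_mean_kg),
                   0.6 * mass_mean_kg)
    intercepts <- rnorm(n_individuals, 0, ranef_sd)
    n <- n_individuals * flights_per_individual
    speed <- runif(n, speed_range[1], speed_range[2])
    ind_idx <- rep(seq_len(n_individuals), each = flights_per_individual)
    power <- k1 * speed^3 + k2 / speed + k3 +
      intercepts[ind_idx] + rnorm(n, 0, noise_sd)
    lift_val <- if (power_type == "mech") masses[ind_idx] * gravity
                else rep(NA_real_, n)
    out <- tibble(
      individual = ids[ind_idx], speed = speed, power = power,
      power_type = power_type, mass_kg = masses[ind_idx],
      body_weight = masses[ind_idx] * gravity,
      lift = lift_val
    )
  })
  attr(out, "truth") <- list(
    k1 = k1, k2 = k2, k3 = k3, ranef_sd = ranef_sd, noise_sd = noise_sd,
    intercepts = setNames(intercepts, ids),
    masses = setNames(masses, ids), seed = seed
  )
  out
}

# Wing morphology allometries for synthetic species (mass in kg).
species_allometry <- function(mass_kg) {
  span <- 1.17 * mass_kg^0.39
  area <- 0.135 * mass_kg^0.72
  list(span = span, area = area)
}

#' Simulate a cross-species metabolic power table
#'
#' Builds a literature-style table of bird and bat species with body masses
#' log-uniform on `mass_range`, wing morphology from mass allometries,
#' wingbeat frequency from its allometric prediction, and metabolic power
#' series constructed as flapping-model mechanical power divided by a true
#' conversion efficiency following the scaling law
#' \deqn{\log_{10}\eta = a \log_{10} M_g + b + b_{sp} + c_{sp}(U - \bar U)
#'   + \varepsilon,}
#' with species random intercepts (`species_sd`), species random speed
#' slopes (`speed_slope_sd`) and residual noise. Speeds span each species'
#' minimum-power speed. Taxon labels are assigned independently of mass and
#' efficiency, so the generated data carry no true bird-bat effect.
#'
#' @param n_species Number of species (>= 5).
#' @param n_bird Number labelled "bird" (the rest are "bat"); defaults to
#'   two-thirds of the species, mirroring the 16:8 bird-bat split of the
#'   published meta-analysis at the default `n_species = 24`.
#' @param slope,intercept True scaling law (mass in g, efficiency in
#'   percent).
#' @param species_sd Species random-intercept sd (log10 units).
#' @param speed_slope_sd Species random speed-slope sd (log10 units per
#'   m s^-1).
#' @param residual_sd Residual sd (log10 units).
#' @param mass_range Body-mass range in kg.
#' @param n_speeds Speeds per species.
#' @param conditions [flight_conditions()].
#' @param seed Optional RNG seed.
#' @return A long tibble (`species`, `taxon`, `mass_kg`, `span_m`,
#'   `area_m2`, `f_hz`, `method`, `speed`, `p_met_w`) with a `truth`
#'   attribute holding the scaling parameters, per-species effects and true
#'   efficiencies.
#' @examples
#' tbl <- simulate_species_table(seed = 1)
#' fit_scaling_model(species_efficiency(tbl))
#' @export
simulate_species_table <- function(n_species = 24,
                                   n_bird = round(2 * n_species / 3),
                                   slope = 0.24, intercept = 0.49,
                                   species_sd = 0.29, speed_slope_sd = 0.03,
                                   residual_sd = 0.02,
                                   mass_range = c(0.004, 2.6), n_speeds = 5,
                                   conditions = flight_conditions(),
                                   seed = NULL) {
  if (n_species < 5) stop_invalid("need at least 5 species.")
  with_local_seed(seed, {
    ids <- sprintf("species%02d", seq_len(n_species))
    taxon <- c(rep("bird", n_bird), rep("bat", n_species - n_bird))
    mass <- exp(runif(n_species, log(mass_range[1]), log(mass_range[2])))
    b_sp <- rnorm(n_species, 0, species_sd)
    c_sp <- rnorm(n_species, 0, speed_slope_sd)
    rows <- purrr::map(seq_len(n_species), function(i) {
      al <- species_allometry(mass[i])
      morph <- morphology(mass[i], al$span, al$area, 1) # placeholder f
      f <- wingbeat_freq_allometric(morph, conditions)
      morph <- morphology(mass[i], al$span, al$area, f)
      mod <- flap_model(morph, conditions)
      u_mp <- minimum_power_speed(mod)
      speeds <- u_mp * seq(0.95, 1.6, length.out = n_speeds)
      mech <- flap_power(morph, conditions, speeds)
      u_bar <- mean(speeds)
      log_eta <- slope * log10(mass[i] * 1000) + intercept + b_sp[i] +
        c_sp[i] * (speeds - u_bar) + rnorm(n_speeds, 0, residual_sd)
      eta_pct <- 10^log_eta
      tibble(
        species = ids[i], taxon = taxon[i], mass_kg = mass[i],
        span_m = al$span, area_m2 = al$area, f_hz = f,
        method = "respirometry", speed = speeds,
        p_met_w = mech$total / (eta_pct / 100),
        eta_true_pct = eta_pct
      )
    })
  })
  out <- bind_rows(rows)
  attr(out, "truth") <- list(
    slope = slope, intercept = intercept, species_sd = species_sd,
    speed_slope_sd = speed_slope_sd, residual_sd = residual_sd,
    species_intercepts = setNames(b_sp, ids),
    speed_slopes = setNames(c_sp, ids), masses = setNames(mass, ids),
    seed = seed
  )
  out
}
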