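# End-to-end orchestration: synthetic wake -> metabolic -> curve fits ->
# efficiency -> meta-analysis, with a run manifest and drop-reason logging.

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Unknown arguments
#' are rejected. `wake`, `metabolic`, `curves`, `efficiency` and `meta`
#' are lists of stage settings merged over the defaults shown.
#'
#' @param seed Master seed; each stage derives its own sub-seed from it.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param out_dir Optional directory for per-stage CSV output.
#' @param morphology List of [morphology()] arguments (defaults: the study
#'   bat).
#' @param environment List of [flight_conditions()] arguments.
#' @param wake Wake-stage settings: `individuals`, `speeds`, `noise_sd`,
#'   `n_wingbeats`, `frames_per_wingbeat`, `n_grid`, `ranef_sd`, and the
#'   true mechanical curve `k1`, `k2`, `k3`.
#' @param metabolic Metabolic-stage settings: `individuals`,
#'   `flights_per_individual`, `speed_range`, `noise_sd`, `ranef_sd`,
#'   `resting_vco2`, `pool_ml`, and the true metabolic curve `k1`, `k2`,
#'   `k3`.
#' @param curves Curve-fit settings: `bin_width`.
#' @param efficiency Efficiency settings: `pairing_tolerance`, `bmr`.
#' @param meta Meta-analysis settings: `n_species`, `n_bird`, `n_speeds`.
#' @return A `pipeline_config` object (named list).
#' @examples
#' cfg <- pipeline_config(seed = 1, stages = c("metabolic", "curves"))
#' @export
pipeline_config <- function(seed = 1,
                            stages = c("wake", "metabolic", "curves",
                                       "efficiency", "meta"),
                            out_dir = NULL,
                            morphology = list(),
                            environment = list(),
                            wake = list(),
                            metabolic = list(),
                            curves = list(),
                            efficiency = list(),
                            meta = list()) {
  known <- c("wake", "metabolic", "curves", "efficiency", "meta")
  if (!all(stages %in% known)) {
    stop_invalid("unknown stage(s): %s",
                 paste(setdiff(stages, known), collapse = ", "))
  }
  merge_block <- function(user, defaults, what) {
    extra <- setdiff(names(user), names(defaults))
    if (length(extra) > 0) {
      stop_invalid("unknown %s setting(s): %s", what,
                   paste(extra, collapse = ", "))
    }
    modifyList(defaults, user)
  }
  cfg <- list(
    seed = seed, stages = stages, out_dir = out_dir,
    morphology = merge_block(morphology, list(
      body_mass = 0.0089, wing_span = 0.23, wing_area = 0.0077,
      wingbeat_freq = 9.9, body_drag_coeff = 0.4), "morphology"),
    environment = merge_block(environment, list(
      air_density = 1.225, gravity = 9.81), "environment"),
    wake = merge_block(wake, list(
      individuals = 4, speeds = c(5, 6, 7, 8, 9), noise_sd = 0.01,
      n_wingbeats = 2, frames_per_wingbeat = 8, n_grid = 73,
      ranef_sd = 0.004, k1 = 9.21e-5, k2 = 0.176, k3 = 0.0297), "wake"),
    metabolic = merge_block(metabolic, list(
      individuals = 8, flights_per_individual = 6, speed_range = c(4, 9),
      noise_sd = 0.005, ranef_sd = 0.05, resting_vco2 = 0.5, pool_ml = 2,
      k1 = 3.73e-4, k2 = 2.52, k3 = 0.490), "metabolic"),
    curves = merge_block(curves, list(bin_width = 1), "curves"),
    efficiency = merge_block(efficiency, list(
      pairing_tolerance = 0.5, bmr = 0.08), "efficiency"),
    meta = merge_block(meta, list(
      n_species = 24, n_bird = 16, n_speeds = 5), "meta")
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose top-level keys are
#'   [pipeline_config()] arguments (unknown keys are rejected).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_data("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(extra) > 0) {
    stop_invalid("unknown config key(s): %s", paste(extra, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

# Circulation/separation solver: find the Lamb-Oseen pair that supports a
# given weight (F = rho U Gamma s) while carrying a target energy flux.
# Flux grows monotonically as s shrinks (Gamma ~ 1/s), so uniroot applies.
vortex_pair_geometry <- function(target_power, weight, freestream, rho,
                                 core_ratio = 0.42,
                                 s_range = c(0.015, 0.12)) {
  flux_at <- function(s) {
    gamma <- weight / (rho * freestream * s)
    hw <- 5 * s
    n <- 161
    yy <- seq(-hw, hw, length.out = n)
    Y <- matrix(yy, n, n); Z <- matrix(yy, n, n, byrow = TRUE)
    f <- lamb_oseen_pair(Y, Z, gamma, s, core_ratio * s)
    rho * freestream * sum(0.5 * (f$v^2 + f$w^2)) * (yy[2] - yy[1])^2
  }
  lo <- flux_at(s_range[2]); hi <- flux_at(s_range[1])
  if (target_power <= lo || target_power >= hi) {
    stop_numeric("target power %.3g W outside attainable range [%.3g, %.3g] W.",
                 target_power, lo, hi)
  }
  s <- uniroot(function(s) flux_at(s) - target_power, s_range,
               tol = 1e-5)$root
  list(separation = s, circulation = weight / (rho * freestream * s),
       core_radius = core_ratio * s)
}

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order on synthetic data generated under
#' the configuration's seed:
#'
#' 1. **wake** — for each individual and speed, builds a vortex-pair wake
#'    whose circulation/separation jointly support the individual's weight
#'    and carry the mechanical-curve energy flux, processes it through
#'    masking/reconstruction/net-drag correction, and applies the
#'    vertical-force selection. Retained sequences become mechanical power
#'    records.
#' 2. **metabolic** — simulates a washout trace per flight (metabolic-curve
#'    CO2 production), estimates flight VCO2 and power, and applies the
#'    flight-fraction / Z-score / individual filters.
#' 3. **curves** — mixed-model U-shaped fits to both record sets (the
#'    mechanical-curve constant pinned at the flapping-model minimum-power
#'    speed).
#' 4. **efficiency** — all four conversion-efficiency estimators plus the
#'    fixed-efficiency underestimation summary.
#' 5. **meta** — synthetic species table, per-species efficiencies and the
#'    efficiency-mass scaling fit.
#'
#' @param config A [pipeline_config()], or a path to a YAML config.
#' @return A `flightpower_run` object: list with stage outputs, a
#'   `manifest` tibble (stage, status, rows, note), `drop_log`, a config
#'   hash and a content hash. If `out_dir` is set, per-stage CSVs are
#'   written.
#' @examples
#' \donttest{
#' run <- run_pipeline(pipeline_config(seed = 1,
#'                                     stages = c("metabolic", "curves")))
#' run$manifest
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  morph <- do.call(morphology, config$morphology)
  cond <- do.call(flight_conditions, config$environment)
  res <- list(config = config, morphology = morph, conditions = cond)
  manifest <- list()
  drop_log <- list()
  note_stage <- function(stage, status, rows, note = "") {
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = stage, status = status, rows = rows, note = note)
  }
  want <- function(s) s %in% config$stages

  if (want("wake")) {
    w <- config$wake
    mech_curve <- power_curve(w$k1, w$k2, w$k3)
    rows <- list()
    seq_tbl <- list()
    idx <- 0
    with_local_seed(config$seed + 101, {
      masses <- pmax(rnorm(w$individuals, morph$body_mass,
                           0.05 * morph$body_mass), 0.8 * morph$body_mass)
      intercepts <- rnorm(w$individuals, 0, w$ranef_sd)
      for (i in seq_len(w$individuals)) {
        weight <- masses[i] * cond$gravity
        for (U in w$speeds) {
          idx <- idx + 1
          target <- predict(mech_curve, U) + intercepts[i]
          geom <- vortex_pair_geometry(target, weight, U, cond$air_density)
          ws <- simulate_vortex_wake(
            circulation = geom$circulation, separation = geom$separation,
            core_radius = geom$core_radius, freestream = U,
            conditions = cond,
            grid_halfwidth = max(0.12, 3 * geom$separation),
            n_grid = w$n_grid, wingbeat_freq = morph$wingbeat_freq,
            n_wingbeats = w$n_wingbeats,
            frames_per_wingbeat = w$frames_per_wingbeat,
            noise_sd = w$noise_sd,
            seed = config$seed * 1000 + idx)
          out <- process_wake_sequence(ws, cond, weight = weight)
          seq_tbl[[idx]] <- out %>%
            mutate(individual = sprintf("bat%02d", i), speed = U,
                   target_power = target, weight = weight)
        }
      }
    })
    wake_results <- bind_rows(seq_tbl)
    mech_records <- wake_results %>%
      filter(.data$retained) %>%
      mutate(power = .data$power_corrected, power_type = "mech",
             body_weight = .data$weight, lift = .data$weight) %>%
      select("individual", "speed", "power", "power_type", "body_weight",
             "lift")
    res$wake_results <- wake_results
    res$mech_records <- mech_records
    drop_log$wake <- wake_results %>%
      filter(!.data$retained) %>%
      mutate(reason = "vertical force outside 20% of weight or < 2 wingbeats") %>%
      select("individual", "speed", "reason")
    note_stage("wake", "ok", nrow(mech_records),
               sprintf("%d/%d sequences retained", nrow(mech_records),
                       nrow(wake_results)))
  }

  if (want("metabolic")) {
    m <- config$metabolic
    met_curve <- power_curve(m$k1, m$k2, m$k3)
    recs <- list()
    with_local_seed(config$seed + 202, {
      intercepts <- rnorm(m$individuals, 0, m$ranef_sd)
      idx <- 0
      for (i in seq_len(m$individuals)) {
        for (j in seq_len(m$flights_per_individual)) {
          idx <- idx + 1
          U <- runif(1, m$speed_range[1], m$speed_range[2])
          p_true <- max(predict(met_curve, U) + intercepts[i], 0.1)
          vco2_true <- p_true * 60 / fuel_model("glycogen")$joules_per_ml_co2
          landing <- if (runif(1) < 0.4) {
            data.frame(start = 10, end = 10 + runif(1, 2, 35))
          } else {
            NULL
          }
          sim <- simulate_washout_trace(
            resting_vco2 = m$resting_vco2, flight_vco2 = vco2_true,
            pool_ml = m$pool_ml, landings = landing,
            noise_sd = m$noise_sd, seed = config$seed * 2000 + idx)
          est <- tryCatch(flight_vco2(sim$trace, sim$event),
                          error = function(e) NULL)
          if (!is.null(est)) {
            recs[[idx]] <- tibble(
              individual = sprintf("bat%02d", i), speed = U,
              p_met = power_from_vco2(est$vco2_flight),
              flight_fraction = est$flight_fraction,
              power_type = "met")
          }
        }
      }
    })
    met_all <- bind_rows(recs)
    met_kept <- filter_flights(met_all,
                               fraction_min = 0.6, z_max = 2,
                               min_flights = 4, bin_width = 1)
    drop_log$metabolic <- attr(met_kept, "drop_log")
    res$met_records <- met_kept %>%
      mutate(power = .data$p_met) %>%
      select("individual", "speed", "power", "power_type",
             "flight_fraction", "z_score")
    note_stage("metabolic", "ok", nrow(res$met_records),
               sprintf("%d/%d flights retained", nrow(res$met_records),
                       nrow(met_all)))
  }

  if (want("curves")) {
    if (is.null(res$met_records) && is.null(res$mech_records)) {
      note_stage("curves", "error", 0, "no upstream records")
      stop_data("stage 'curves' requires wake and/or metabolic records.")
    }
    u_mp_flap <- minimum_power_speed(flap_model(morph, cond))
    if (!is.null(res$mech_records) && nrow(res$mech_records) >= 4) {
      res$mech_fit <- fit_power_curve(res$mech_records, k3 = "fixed",
                                      u_mp_prior = u_mp_flap,
                                      bin_width = config$curves$bin_width)
    }
    if (!is.null(res$met_records) && nrow(res$met_records) >= 4) {
      res$met_fit <- fit_power_curve(res$met_records, k3 = "fixed",
                                     u_mp_prior = u_mp_flap,
                                     bin_width = config$curves$bin_width)
      res$met_vs_linear <- compare_to_linear(res$met_records,
                                             u_mp_prior = u_mp_flap,
                                             curve_fit = res$met_fit)
    }
    note_stage("curves", "ok",
               sum(!is.null(res$mech_fit), !is.null(res$met_fit)),
               sprintf("k3 pinned at U_mp prior %.1f m/s", u_mp_flap))
  }

  if (want("efficiency")) {
    if (is.null(res$mech_records) || is.null(res$met_records)) {
      note_stage("efficiency", "error", 0, "needs wake and metabolic stages")
      stop_data("stage 'efficiency' requires both record sets.")
    }
    e <- config$efficiency
    eff_tabs <- bind_rows(
      efficiency_mean(res$mech_records, res$met_records),
      efficiency_median_vonbusse(res$mech_records, res$met_records)
    )
    if (!is.null(res$mech_fit) && !is.null(res$met_fit)) {
      speeds <- sort(unique(round_to(res$mech_records$speed, 1)))
      eff_tabs <- bind_rows(
        eff_tabs,
        efficiency_model_ratio(res$mech_fit, res$met_fit, speeds) %>%
          select("speed_bin", "method", "efficiency"))
      res$underestimation <- underestimation_stats(
        res$met_records, res$mech_fit, bmr = e$bmr)
    }
    res$efficiency <- eff_tabs
    res$efficiency_pairs <- efficiency_individual_pairs(
      res$mech_records, res$met_records, tolerance = e$pairing_tolerance)
    note_stage("efficiency", "ok", nrow(eff_tabs),
               sprintf("%d individual pairs", nrow(res$efficiency_pairs$pairs)))
  }

  if (want("meta")) {
    mt <- config$meta
    species <- simulate_species_table(
      n_species = mt$n_species, n_bird = mt$n_bird, n_speeds = mt$n_speeds,
      conditions = cond, seed = config$seed + 303)
    est <- species_efficiency(species, cond)
    res$species_table <- species
    res$species_efficiency <- est
    res$scaling_fit <- fit_scaling_model(est)
    res$near_ump <- near_ump_comparison(est)
    note_stage("meta", "ok", nrow(est),
               sprintf("slope %.3f", res$scaling_fit$slope))
  }

  res$manifest <- bind_rows(manifest)
  res$drop_log <- bind_rows(drop_log, .id = "stage_of_drop")
  res$config_hash <- rlang::hash(unclass(config))
  res$content_hash <- rlang::hash(res[intersect(
    c("wake_results", "mech_records", "met_records", "efficiency",
      "species_efficiency"), names(res))])
  out <- structure(res, class = "flightpower_run")
  if (!is.null(config$out_dir)) report_tables(out, config$out_dir)
  out
}

#' @export
print.flightpower_run <- function(x, ...) {
  cat("<flightpower_run>\n")
  print(x$manifest)
  invisible(x)
}

#' Write figure-style summary tables from a pipeline run
#'
#' Emits tidy CSVs mirroring the study's main panels: power versus speed
#' (records and fitted curves), conversion efficiency versus speed (all
#' estimators), and efficiency versus body mass (meta-analysis species
#' means). Tables for stages that did not run are skipped with a message.
#'
#' @param run A `flightpower_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the tibbles written.
#' @export
report_tables <- function(run, out_dir) {
  stopifnot(inherits(run, "flightpower_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()

  power_tab <- bind_rows(
    if (!is.null(run$mech_records))
      mutate(run$mech_records, power_type = "mech"),
    if (!is.null(run$met_records))
      run$met_records %>% mutate(power_type = "met")
  )
  if (!is.null(power_tab) && nrow(power_tab) > 0) {
    curves <- list()
    grid <- seq(min(power_tab$speed), max(power_tab$speed), by = 0.1)
    if (!is.null(run$mech_fit) && !is.null(run$mech_fit$curve)) {
      curves$mech <- tibble(speed = grid, power_type = "mech",
                            fitted = predict(run$mech_fit, grid))
    }
    if (!is.null(run$met_fit) && !is.null(run$met_fit$curve)) {
      curves$met <- tibble(speed = grid, power_type = "met",
                           fitted = predict(run$met_fit, grid))
    }
    written$power_vs_speed <- power_tab %>%
      select("individual", "speed", "power", "power_type")
    readr::write_csv(written$power_vs_speed,
                     file.path(out_dir, "power_vs_speed.csv"))
    if (length(curves) > 0) {
      written$power_curves <- bind_rows(curves)
      readr::write_csv(written$power_curves,
                       file.path(out_dir, "power_curves.csv"))
    }
  }

  if (!is.null(run$efficiency) && nrow(run$efficiency) > 0) {
    written$efficiency_vs_speed <- run$efficiency
    readr::write_csv(run$efficiency,
                     file.path(out_dir, "efficiency_vs_speed.csv"))
  } else {
    inform("efficiency stage absent; efficiency_vs_speed.csv not written.")
  }

  if (!is.null(run$species_efficiency)) {
    written$efficiency_vs_mass <- run$species_efficiency %>%
      group_by(.data$species, .data$taxon, .data$mass_kg) %>%
      summarise(eff_min = min(.data$efficiency_pct),
                eff_max = max(.data$efficiency_pct),
                efficiency_pct = mean(.data$efficiency_pct),
                .groups = "drop")
    readr::write_csv(written$efficiency_vs_mass,
                     file.path(out_dir, "efficiency_vs_mass.csv"))
  }

  readr::write_csv(run$manifest, file.path(out_dir, "manifest.csv"))
  if (!is.null(run$drop_log) && nrow(run$drop_log) > 0) {
    readr::write_csv(run$drop_log, file.path(out_dir, "drop_log.csv"))
  }
  invisible(written)
}
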