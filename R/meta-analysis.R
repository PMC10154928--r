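# Cross-species conversion-efficiency meta-analysis: estimate efficiency for
# bird and bat species from literature metabolic data and modelled mechanical
# power, then fit the efficiency-body-mass scaling law.

#' Convert oxygen consumption to watts
#'
#' @param vo2 Oxygen consumption in ml min^-1 (non-negative).
#' @param oxyjoule Oxyjoule equivalent in J ml^-1 O2 (default 20.1).
#' @return Power in W.
#' @examples
#' vo2_to_watts(3) # 1.005 W
#' @export
vo2_to_watts <- function(vo2, oxyjoule = 20.1) {
  check_positive(vo2, "vo2", allow_zero = TRUE)
  vo2 / 60 * oxyjoule
}

#' @rdname vo2_to_watts
#' @param watts Power in W.
#' @export
watts_to_vo2 <- function(watts, oxyjoule = 20.1) watts * 60 / oxyjoule

# Fit the cubic-plus-inverse family to one species' metabolic series by OLS
# (one "individual", no random effects); k3 dropped for short series.
fit_species_met_curve <- function(speed, p_met) {
  if (length(speed) < 2) stop_data("need at least 2 speeds per species.")
  d <- data.frame(U = speed, P = p_met)
  cf <- if (length(speed) >= 4) {
    coef(lm(P ~ I(U^3) + I(1 / U), data = d))
  } else {
    c(0, coef(lm(P ~ 0 + I(U^3) + I(1 / U), data = d)))
  }
  k1 <- unname(cf[["I(U^3)"]]); k2 <- unname(cf[["I(1/U)"]])
  if (!is.finite(k1) || !is.finite(k2) || k1 <= 0 || k2 <= 0) {
    # degenerate series: fall back to the speed of minimum observed power
    return(list(curve = NULL, u_mp = speed[which.min(p_met)]))
  }
  list(curve = power_curve(k1, k2, max(unname(cf[[1]]), 0)),
       u_mp = (k2 / (3 * k1))^0.25)
}

#' Per-species conversion efficiency from literature metabolic data
#'
#' For each species, models mechanical power across its measured speeds
#' with the flapping-flight model ([flap_power()]) built from the species'
#' morphology, and divides into the measured metabolic power:
#' \eqn{\eta(U) = P_{mech}(U) / P_{met}(U)}. Two quality filters mirror the
#' meta-analysis protocol: speeds below the species' metabolic
#' minimum-power speed (from a cubic-plus-inverse fit to its metabolic
#' series) are excluded, as are speeds red-flagged by the flapping model.
#'
#' @param species_tbl Long tibble with one row per species x speed:
#'   columns `species`, `taxon` ("bird"/"bat"), `mass_kg`, `span_m`,
#'   `area_m2`, `f_hz`, `speed`, and `p_met_w` (W) or `vo2_ml_min`.
#' @param conditions A [flight_conditions()].
#' @param body_drag_coeff Body drag coefficient used for all species.
#' @param ump_scale Scale factor on the minimum-power-speed filter
#'   threshold (speeds below `ump_scale * u_mp_met` are excluded); 1 is the
#'   protocol value, lower values relax the filter monotonically.
#' @return A tibble with one row per retained species x speed:
#'   `species`, `taxon`, `mass_kg`, `speed`, `p_met`, `p_mech`,
#'   `efficiency_pct` and `u_mp_met`. Species with no retained speeds are
#'   dropped with a message.
#' @examples
#' tbl <- simulate_species_table(n_species = 6, seed = 1)
#' species_efficiency(tbl)
#' @export
species_efficiency <- function(species_tbl, conditions = flight_conditions(),
                               body_drag_coeff = 0.4, ump_scale = 1) {
  check_columns(species_tbl,
                c("species", "taxon", "mass_kg", "span_m", "area_m2", "f_hz",
                  "speed"), "species table")
  d <- as_tibble(species_tbl)
  if (!"p_met_w" %in% names(d)) {
    check_columns(d, "vo2_ml_min", "species table")
    d$p_met_w <- vo2_to_watts(d$vo2_ml_min)
  }
  out <- d %>%
    group_by(.data$species) %>%
    dplyr::group_modify(function(g, key) {
      morph <- morphology(g$mass_kg[1], g$span_m[1], g$area_m2[1], g$f_hz[1],
                          body_drag_coeff = body_drag_coeff)
      met_fit <- fit_species_met_curve(g$speed, g$p_met_w)
      mech <- flap_power(morph, conditions, g$speed)
      res <- g %>%
        mutate(p_mech = mech$total, flagged = mech$any_flag,
               u_mp_met = met_fit$u_mp) %>%
        filter(.data$speed >= ump_scale * .data$u_mp_met, !.data$flagged) %>%
        mutate(efficiency_pct = 100 * .data$p_mech / .data$p_met_w)
      if (nrow(res) == 0) {
        inform(sprintf("species '%s': all speeds filtered (below U_mp,met or flagged).",
                       key$species))
      }
      res
    }) %>%
    ungroup() %>%
    select("species", "taxon", "mass_kg", "speed", p_met = "p_met_w",
           "p_mech", "efficiency_pct", "u_mp_met")
  out
}

#' Fit the efficiency-body-mass scaling model
#'
#' Gaussian mixed model on log10 conversion efficiency (in percent) with
#' fixed log10 body mass (in grams), optionally taxon (bird/bat), and
#' flight speed (centred within species), with a random intercept and a
#' random speed slope per species:
#' \deqn{\log_{10}\eta = \beta_0 + \beta_1 \log_{10} M + \beta_2 U_c
#'   (+ \beta_3\,\mathrm{taxon}) + b_{0,sp} + b_{1,sp} U_c + \varepsilon.}
#' If the random-slope fit is singular or fails to converge the model is
#' refit with the random intercept only and flagged.
#'
#' @param estimates Tibble from [species_efficiency()] (columns `species`,
#'   `taxon`, `mass_kg`, `speed`, `efficiency_pct`).
#' @param include_taxon Include the bird/bat fixed effect (default `FALSE`,
#'   matching the pooled scaling law).
#' @param center_speed Centre speed within species before fitting (keeps
#'   the intercept interpretable at each species' typical speed).
#' @return An object of class `efficiency_scaling`: list with `slope`
#'   (mass exponent), `intercept`, fixed-effect table (Wald z tests),
#'   random-effect sds, the `glmmTMB` fit, and flags. Supports `tidy()`,
#'   `glance()`, [predict_efficiency()] and [autoplot()].
#' @examples
#' est <- species_efficiency(simulate_species_table(seed = 1))
#' fit <- fit_scaling_model(est)
#' tidy(fit)
#' @export
fit_scaling_model <- function(estimates, include_taxon = FALSE,
                              center_speed = TRUE) {
  check_columns(estimates, c("species", "mass_kg", "speed", "efficiency_pct"),
                "efficiency estimates")
  d <- as_tibble(estimates) %>%
    filter(.data$efficiency_pct > 0) %>%
    mutate(log_eta = log10(.data$efficiency_pct),
           log_mass = log10(.data$mass_kg * 1000))
  if (length(unique(d$species)) < 5) {
    stop_data("need at least 5 species for the scaling model.")
  }
  if (center_speed) {
    d <- d %>% group_by(.data$species) %>%
      mutate(speed_c = .data$speed - mean(.data$speed)) %>% ungroup()
  } else {
    d$speed_c <- d$speed
  }
  if (include_taxon && length(unique(d$taxon)) < 2) {
    stop_data("taxon effect requested but only one taxon present.")
  }
  rhs <- paste("log_eta ~ log_mass + speed_c",
               if (include_taxon) "+ taxon" else "")
  form_full <- as.formula(paste(rhs, "+ (1 + speed_c | species)"))
  form_simple <- as.formula(paste(rhs, "+ (1 | species)"))

  tmb_ok <- function(f) {
    !is.null(f) && isTRUE(f$sdr$pdHess) &&
      all(is.finite(glmmTMB::fixef(f)$cond))
  }
  fit <- suppressWarnings(
    tryCatch(glmmTMB::glmmTMB(form_full, data = d, REML = FALSE),
             error = function(e) NULL))
  simplified <- "none"
  if (!tmb_ok(fit)) {
    fit <- suppressWarnings(
      tryCatch(glmmTMB::glmmTMB(form_simple, data = d, REML = FALSE),
               error = function(e) NULL))
    simplified <- "intercept_only"
    inform("random speed slope dropped (singular or non-converged fit).")
  }
  if (!tmb_ok(fit)) {
    # degenerate data (e.g. an exact line): pooled least squares
    fit <- lm(as.formula(rhs), data = d)
    simplified <- "pooled_lm"
    inform("random effects unidentifiable; pooled least-squares fit used.")
  }
  if (inherits(fit, "glmmTMB")) {
    sm <- summary(fit)$coefficients$cond
    fixed <- tibble(
      term = rownames(sm), estimate = sm[, "Estimate"],
      std_error = sm[, "Std. Error"], statistic = sm[, "z value"],
      p_value = sm[, "Pr(>|z|)"]
    )
    vc <- glmmTMB::VarCorr(fit)$cond$species
    sds <- attr(vc, "stddev")
  } else {
    sm <- suppressWarnings(summary(fit))$coefficients
    fixed <- tibble(
      term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
      statistic = sm[, 3], p_value = sm[, 4]
    )
    sds <- c("(Intercept)" = 0)
  }
  structure(
    list(slope = unname(fixed$estimate[fixed$term == "log_mass"]),
         slope_se = unname(fixed$std_error[fixed$term == "log_mass"]),
         intercept = unname(fixed$estimate[fixed$term == "(Intercept)"]),
         fixed = fixed,
         species_intercept_sd = unname(sds["(Intercept)"]),
         speed_slope_sd = if ("speed_c" %in% names(sds))
           unname(sds["speed_c"]) else NA_real_,
         sigma = stats::sigma(fit),
         n_obs = nrow(d), n_species = length(unique(d$species)),
         include_taxon = include_taxon, simplified = simplified,
         fit = fit, data = d),
    class = "efficiency_scaling"
  )
}

#' @export
print.efficiency_scaling <- function(x, ...) {
  cat(sprintf(
    "<efficiency_scaling> log10(eta%%) = %.2f log10(M g) + %.2f  (%d species, %d obs)\n",
    x$slope, x$intercept, x$n_species, x$n_obs))
  cat(sprintf("  species intercept sd %.3g, speed slope sd %s%s\n",
              x$species_intercept_sd,
              ifelse(is.na(x$speed_slope_sd), "-",
                     sprintf("%.3g", x$speed_slope_sd)),
              if (!identical(x$simplified, "none")) {
                sprintf(" (simplified: %s)", x$simplified)
              } else {
                ""
              }))
  invisible(x)
}

#' @method tidy efficiency_scaling
#' @export
tidy.efficiency_scaling <- function(x, ...) x$fixed

#' @method glance efficiency_scaling
#' @export
glance.efficiency_scaling <- function(x, ...) {
  tibble(
    slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
    species_intercept_sd = x$species_intercept_sd,
    speed_slope_sd = x$speed_slope_sd, sigma = x$sigma,
    n_obs = x$n_obs, n_species = x$n_species,
    logLik = as.numeric(logLik(x$fit)), simplified = x$simplified
  )
}

#' Predicted conversion efficiency at a given body mass
#'
#' Evaluates the scaling law \eqn{\eta = 10^{a \log_{10} M + b}} (mass in
#' grams, efficiency in percent).
#'
#' @param mass_g Body mass in grams.
#' @param fit An `efficiency_scaling` fit, or `NULL` to use `slope` and
#'   `intercept` directly.
#' @param slope,intercept Coefficients used when `fit` is `NULL`.
#' @return Predicted efficiency in percent.
#' @examples
#' predict_efficiency(7.6) # ~5%
#' @export
predict_efficiency <- function(mass_g, fit = NULL, slope = 0.24,
                               intercept = 0.49) {
  check_positive(mass_g, "mass_g")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "efficiency_scaling"))
    slope <- fit$slope
    intercept <- fit$intercept
  }
  10^(slope * log10(mass_g) + intercept)
}

#' Mass-corrected conversion efficiency
#'
#' Removes the allometric trend by dividing efficiency by
#' \eqn{M^{exponent}} (mass in grams; exponent from the fitted scaling
#' model, 0.24 by default).
#'
#' @param efficiency Efficiency values (percent or fraction; units are
#'   preserved).
#' @param mass_g Body mass in grams.
#' @param exponent Scaling exponent.
#' @return Mass-corrected efficiency.
#' @examples
#' mass_correct(9.2, 7.6) # ~5.7
#' @export
mass_correct <- function(efficiency, mass_g, exponent = 0.24) {
  check_positive(mass_g, "mass_g")
  efficiency / mass_g^exponent
}

#' Bird-bat comparison of efficiency near minimum power speed
#'
#' Restricts efficiency estimates to within `window` m s^-1 of each
#' species' metabolic minimum-power speed, averages per species, and (when
#' both taxa are present) tests the taxon contrast with a linear model
#' including the body-mass interaction.
#'
#' @param estimates Tibble from [species_efficiency()] (needs `u_mp_met`).
#' @param window Half-width of the speed window in m s^-1 (default 1).
#' @return A list with `species_means` (per-species window means),
#'   `group_summary` (mean, sd, se, n per taxon) and `test` (taxon term of
#'   the linear model, or `NULL` for a single taxon).
#' @examples
#' est <- species_efficiency(simulate_species_table(seed = 1))
#' near_ump_comparison(est)$group_summary
#' @export
near_ump_comparison <- function(estimates, window = 1) {
  check_columns(estimates, c("species", "taxon", "mass_kg", "speed",
                             "efficiency_pct", "u_mp_met"),
                "efficiency estimates")
  win <- as_tibble(estimates) %>%
    filter(abs(.data$speed - .data$u_mp_met) <= window)
  dropped <- setdiff(unique(estimates$species), unique(win$species))
  if (length(dropped) > 0) {
    inform(sprintf("species without estimates in the U_mp window: %s",
                   paste(dropped, collapse = ", ")))
  }
  species_means <- win %>%
    group_by(.data$species, .data$taxon) %>%
    summarise(mass_kg = .data$mass_kg[1],
              efficiency_pct = mean(.data$efficiency_pct),
              n = n(), .groups = "drop")
  group_summary <- species_means %>%
    group_by(.data$taxon) %>%
    summarise(mean_pct = mean(.data$efficiency_pct),
              sd_pct = sd(.data$efficiency_pct),
              se_pct = sd(.data$efficiency_pct) / sqrt(n()),
              n_species = n(), .groups = "drop")
  test <- NULL
  if (length(unique(species_means$taxon)) > 1 && nrow(species_means) > 3) {
    # centre log mass so the taxon main effect is the contrast at the
    # mean body mass rather than at an extrapolated 1 g
    species_means$log_mass_c <- log10(species_means$mass_kg * 1000) -
      mean(log10(species_means$mass_kg * 1000))
    lmfit <- lm(efficiency_pct ~ log_mass_c * taxon, data = species_means)
    sm <- summary(lmfit)$coefficients
    taxon_rows <- grepl("^taxon", rownames(sm)) & !grepl(":", rownames(sm))
    if (any(taxon_rows)) {
      test <- tibble(term = rownames(sm)[taxon_rows],
                     estimate = sm[taxon_rows, 1],
                     std_error = sm[taxon_rows, 2],
                     statistic = sm[taxon_rows, 3],
                     p_value = sm[taxon_rows, 4])
    }
  }
  list(species_means = species_means, group_summary = group_summary,
       test = test)
}
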