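# Whole-animal and flight-muscle conversion efficiency estimators.
#
# Conversion efficiency is eta = P_mech / P_met. Four estimators are
# provided, differing in how mechanical and metabolic records are matched:
# bin means, bin mean-over-median, fitted-model ratio, and within-individual
# speed pairing.

bin_speeds <- function(x, width) round_to(x, width)

check_power_records <- function(df, what) {
  check_columns(df, c("speed", "power"), what)
  as_tibble(df)
}

#' Conversion efficiency from speed-bin means
#'
#' Rounds air speeds to the nearest `bin_width`, then divides the mean
#' mechanical power by the mean metabolic power in each bin present in both
#' record sets.
#'
#' @param mech,met Tibbles of mechanical and metabolic flight records with
#'   columns `speed` (m s^-1) and `power` (W).
#' @param bin_width Speed bin width in m s^-1 (default 1).
#' @return A tibble with `speed_bin`, `method`, `efficiency` (fraction),
#'   `n_mech`, `n_met`. Bins with only one power type are skipped with a
#'   message.
#' @examples
#' mech <- tibble::tibble(speed = c(6, 6.2), power = c(0.09, 0.094))
#' met <- tibble::tibble(speed = c(5.9, 6.1), power = c(1.0, 1.0))
#' efficiency_mean(mech, met)
#' @export
efficiency_mean <- function(mech, met, bin_width = 1) {
  efficiency_binned(mech, met, bin_width, centre = mean, method = "mean")
}

#' Conversion efficiency with median metabolic power
#'
#' The comparison variant of [efficiency_mean()]: mean mechanical power in
#' each integer-speed bin divided by the *median* metabolic power at that
#' speed, robust to right-skewed metabolic costs.
#'
#' @inheritParams efficiency_mean
#' @return As [efficiency_mean()], with `method = "median_vonbusse"`.
#' @export
efficiency_median_vonbusse <- function(mech, met, bin_width = 1) {
  efficiency_binned(mech, met, bin_width, centre = median,
                    method = "median_vonbusse")
}

efficiency_binned <- function(mech, met, bin_width, centre, method) {
  mech <- check_power_records(mech, "mechanical records")
  met <- check_power_records(met, "metabolic records")
  mech_b <- mech %>%
    group_by(speed_bin = bin_speeds(.data$speed, bin_width)) %>%
    summarise(p_mech = mean(.data$power), n_mech = n(), .groups = "drop")
  met_b <- met %>%
    group_by(speed_bin = bin_speeds(.data$speed, bin_width)) %>%
    summarise(p_met = centre(.data$power), n_met = n(), .groups = "drop")
  skipped <- union(setdiff(mech_b$speed_bin, met_b$speed_bin),
                   setdiff(met_b$speed_bin, mech_b$speed_bin))
  if (length(skipped) > 0) {
    inform(sprintf("skipping speed bin(s) with a single power type: %s",
                   paste(sort(skipped), collapse = ", ")))
  }
  mech_b %>%
    dplyr::inner_join(met_b, by = "speed_bin") %>%
    mutate(method = method, efficiency = .data$p_mech / .data$p_met) %>%
    select("speed_bin", "method", "efficiency", "n_mech", "n_met")
}

#' Conversion efficiency from fitted power curves
#'
#' Evaluates fitted mechanical and metabolic power curves on a speed grid
#' and returns their ratio \eqn{\eta(U) = P_{mech}(U)/P_{met}(U)}.
#'
#' @param mech_fit,met_fit [power_curve()] or [fit_power_curve()] objects
#'   for mechanical and metabolic power.
#' @param speeds Speed grid in m s^-1.
#' @param support Optional numeric range of the fits' data support; speeds
#'   outside it trigger an extrapolation warning.
#' @return A tibble with `speed_bin`, `method = "model_ratio"`,
#'   `efficiency`, `p_mech`, `p_met`.
#' @examples
#' efficiency_model_ratio(power_curve(9.21e-5, 0.176, 0.0297),
#'                        power_curve(3.73e-4, 2.52, 0.490), 5:9)
#' @export
efficiency_model_ratio <- function(mech_fit, met_fit, speeds,
                                   support = NULL) {
  check_positive(speeds, "speeds")
  if (!is.null(support) &&
      (min(speeds) < support[1] || max(speeds) > support[2])) {
    warn("some speeds lie outside the fitted data support; ratios are extrapolated.")
  }
  f_mech <- as_power_function(mech_fit)
  f_met <- as_power_function(met_fit)
  p_mech <- f_mech(speeds)
  p_met <- f_met(speeds)
  tibble(speed_bin = speeds, method = "model_ratio",
         efficiency = p_mech / p_met, p_mech = p_mech, p_met = p_met)
}

#' Conversion efficiency from within-individual speed pairs
#'
#' Pairs every mechanical with every metabolic record of the same
#' individual measured within `tolerance` m s^-1 of each other, computes a
#' per-pair efficiency at the mean pair speed, summarises pairs as median
#' and range per individual per half-m s^-1 speed bin, and reports the
#' Pearson correlation between efficiency and air speed across pairs.
#' Because records enter multiple pairs the pair-level data are not
#' independent; the duplication counts are reported.
#'
#' @param mech,met Record tibbles with columns `individual`, `speed`,
#'   `power`.
#' @param tolerance Maximal speed difference within a pair (m s^-1).
#' @param summary_bin Bin width (m s^-1) for the per-individual summaries.
#' @return An object of class `efficiency_pairs`: list with `pairs`
#'   (pair-level tibble), `summary` (median and range per individual per
#'   bin), and `correlation` (Pearson r, r^2, p, n). `tidy()` returns the
#'   pair tibble, `glance()` the correlation and duplication counts.
#' @examples
#' recs <- simulate_power_records(n_individuals = 3, seed = 2)
#' mech <- dplyr::mutate(recs, power = power * 0.09)
#' eff <- efficiency_individual_pairs(mech, recs)
#' glance(eff)
#' @export
efficiency_individual_pairs <- function(mech, met, tolerance = 0.5,
                                        summary_bin = 0.5) {
  mech <- check_power_records(mech, "mechanical records")
  met <- check_power_records(met, "metabolic records")
  check_columns(mech, "individual", "mechanical records")
  check_columns(met, "individual", "metabolic records")
  mech <- mech %>% mutate(.mech_id = row_number())
  met <- met %>% mutate(.met_id = row_number())
  pairs <- dplyr::inner_join(
    mech %>% select("individual", mech_speed = "speed", p_mech = "power",
                    ".mech_id"),
    met %>% select("individual", met_speed = "speed", p_met = "power",
                   ".met_id"),
    by = "individual", relationship = "many-to-many") %>%
    filter(abs(.data$mech_speed - .data$met_speed) <= tolerance) %>%
    mutate(speed = (.data$mech_speed + .data$met_speed) / 2,
           efficiency = .data$p_mech / .data$p_met)
  if (nrow(pairs) == 0) {
    inform("no within-individual speed pairs found.")
    return(structure(list(pairs = pairs, summary = tibble(),
                          correlation = NULL),
                     class = "efficiency_pairs"))
  }
  summary <- pairs %>%
    group_by(.data$individual,
             speed_bin = bin_speeds(.data$speed, summary_bin)) %>%
    summarise(efficiency_median = median(.data$efficiency),
              efficiency_min = min(.data$efficiency),
              efficiency_max = max(.data$efficiency),
              n_pairs = n(), .groups = "drop")
  corr <- if (nrow(pairs) >= 3 && sd(pairs$speed) > 0) {
    ct <- cor.test(pairs$speed, pairs$efficiency)
    list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
         p_value = ct$p.value, n = nrow(pairs))
  } else {
    NULL
  }
  dup <- function(ids) sum(table(ids) > 1)
  structure(
    list(pairs = pairs, summary = summary, correlation = corr,
         n_mech_duplicated = dup(pairs$.mech_id),
         n_met_duplicated = dup(pairs$.met_id),
         tolerance = tolerance),
    class = "efficiency_pairs"
  )
}

#' @export
print.efficiency_pairs <- function(x, ...) {
  cat(sprintf("<efficiency_pairs> %d pairs (+/- %.2g m/s)\n",
              nrow(x$pairs), x$tolerance))
  if (!is.null(x$correlation)) {
    cat(sprintf("  efficiency vs speed: r^2 = %.2f, p = %.3g\n",
                x$correlation$r_squared, x$correlation$p_value))
  }
  invisible(x)
}

#' @method tidy efficiency_pairs
#' @export
tidy.efficiency_pairs <- function(x, ...) x$pairs

#' @method glance efficiency_pairs
#' @export
glance.efficiency_pairs <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_mech_duplicated = x$n_mech_duplicated %||% 0L,
    n_met_duplicated = x$n_met_duplicated %||% 0L,
    r = x$correlation$r %||% NA_real_,
    r_squared = x$correlation$r_squared %||% NA_real_,
    p_value = x$correlation$p_value %||% NA_real_
  )
}

#' Flight-muscle conversion efficiency
#'
#' Efficiency of the flight muscles after removing basal costs:
#' \deqn{\eta_{fm} = 1.1\,P_{mech} / (P_{met} - BMR)}
#' (convention `"overhead_on_mech"`, the default). The alternative
#' `"strict_inverse"` is the exact algebraic inverse of the
#' mechanical-to-metabolic prediction,
#' \eqn{\eta = 1.1 P_{mech}/(P_{met} - 1.1\,BMR)}.
#'
#' @param p_met Metabolic power in W; must exceed `bmr`.
#' @param bmr Basal metabolic rate in W.
#' @param p_mech Mechanical power in W.
#' @param convention `"overhead_on_mech"` or `"strict_inverse"`.
#' @param overhead Respiratory/circulatory overhead factor.
#' @return Muscle efficiency (fraction).
#' @examples
#' muscle_efficiency(1.0, 0.08, 0.092) # ~0.11
#' @export
muscle_efficiency <- function(p_met, bmr, p_mech,
                              convention = c("overhead_on_mech",
                                             "strict_inverse"),
                              overhead = 1.1) {
  convention <- match.arg(convention)
  if (any(p_met <= bmr)) stop_invalid("`p_met` must exceed `bmr`.")
  switch(convention,
    overhead_on_mech = overhead * p_mech / (p_met - bmr),
    strict_inverse = efficiency_from_powers(p_met, p_mech, bmr, overhead)
  )
}

#' Underestimation of measured metabolic power by the fixed-efficiency model
#'
#' For each measured metabolic record, predicts metabolic power from the
#' fitted mechanical curve via [predict_met_from_mech()] (conversion
#' efficiency 23% by convention) and reports the percentage by which the
#' prediction falls short of the measurement.
#'
#' @param met Tibble of measured metabolic records (`speed`, `power`).
#' @param mech_fit Mechanical power curve or fit, evaluated at each
#'   record's speed.
#' @param bmr Basal metabolic rate in W.
#' @param efficiency Assumed conversion efficiency (default 0.23).
#' @param overhead Overhead factor (default 1.1).
#' @return A tibble with per-record `predicted`, `underestimate_pct`
#'   (`100 (measured - predicted)/measured`), plus a `summary` attribute
#'   with mean and range.
#' @examples
#' met <- tibble::tibble(speed = 6, power = 1)
#' underestimation_stats(met, power_curve(9.21e-5, 0.176, 0.0297), bmr = 0.08)
#' @export
underestimation_stats <- function(met, mech_fit, bmr, efficiency = 0.23,
                                  overhead = 1.1) {
  met <- check_power_records(met, "metabolic records")
  f <- as_power_function(mech_fit)
  out <- met %>%
    mutate(
      predicted = predict_met_from_mech(f(.data$speed), bmr,
                                        efficiency, overhead),
      underestimate_pct = 100 * (.data$power - .data$predicted) / .data$power
    )
  attr(out, "summary") <- tibble(
    mean_pct = mean(out$underestimate_pct),
    min_pct = min(out$underestimate_pct),
    max_pct = max(out$underestimate_pct)
  )
  out
}
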