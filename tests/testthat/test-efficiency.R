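# Conversion-efficiency estimators: bin means, median variant, model ratio,
# individual pairing, muscle efficiency, fixed-efficiency underestimation.

test_that("bin-mean efficiency equals spreadsheet arithmetic on a hand fixture", {
  mech <- tibble::tibble(speed = c(5.9, 6.1, 6.3), power = c(0.08, 0.09, 0.10))
  met <- tibble::tibble(speed = c(5.8, 6.0, 6.4), power = c(0.9, 1.0, 1.1))
  out <- efficiency_mean(mech, met)
  expect_equal(out$speed_bin, 6)
  expect_equal(out$efficiency, mean(c(0.08, 0.09, 0.10)) / mean(c(0.9, 1, 1.1)))
  expect_equal(out$n_mech, 3L)
  expect_equal(out$n_met, 3L)
  # the study's bin means: 0.092 W over 1.0 W is ~9.2%
  out2 <- efficiency_mean(tibble::tibble(speed = 6, power = 0.092),
                          tibble::tibble(speed = 6, power = 1.0))
  expect_equal(out2$efficiency, 0.092)
  # equal powers give unit efficiency
  same <- tibble::tibble(speed = 6, power = 1)
  expect_equal(efficiency_mean(same, same)$efficiency, 1)
  # a bin present in only one record set is skipped with a message
  expect_message(
    efficiency_mean(tibble::tibble(speed = c(6, 9), power = 0.09),
                    tibble::tibble(speed = 6, power = 1)),
    "skipping")
})

test_that("the median variant is robust to skewed metabolic costs", {
  mech <- tibble::tibble(speed = 6, power = 0.08)
  met_sym <- tibble::tibble(speed = rep(6, 3), power = c(0.9, 1.0, 1.1))
  expect_equal(efficiency_median_vonbusse(mech, met_sym)$efficiency,
               efficiency_mean(mech, met_sym)$efficiency)
  met_skew <- tibble::tibble(speed = rep(6, 3), power = c(0.9, 1.0, 1.3))
  expect_equal(efficiency_median_vonbusse(mech, met_skew)$efficiency, 0.08)
  expect_gt(efficiency_median_vonbusse(mech, met_skew)$efficiency,
            efficiency_mean(mech, met_skew)$efficiency)
})

test_that("model-ratio efficiency reproduces the published-curve pattern", {
  out <- efficiency_model_ratio(mech_curve(), met_curve(), 5:9)
  expect_lt(abs(100 * mean(out$efficiency) - 9), 0.5)
  expect_true(all(diff(out$efficiency) > 0)) # strictly increasing on 5-9
  expect_true(all(out$efficiency > 0.07 & out$efficiency < 0.12))
  # identical curves give unit ratio everywhere
  same <- efficiency_model_ratio(met_curve(), met_curve(), 4:9)
  expect_equal(same$efficiency, rep(1, 6))
  expect_warning(
    efficiency_model_ratio(mech_curve(), met_curve(), 12, support = c(5, 9)),
    "extrapolated")
})

test_that("individual pairing honours the speed tolerance and matches brute force", {
  mech <- tibble::tibble(individual = "a", speed = 5.0, power = 0.08)
  met <- tibble::tibble(individual = "a", speed = c(5.4, 5.6), power = 1)
  out <- efficiency_individual_pairs(mech, met)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$pairs$met_speed, 5.4)
  expect_equal(out$pairs$speed, 5.2)

  mech2 <- tibble::tibble(individual = rep(c("a", "b"), each = 3),
                          speed = rep(c(5, 6, 7), 2),
                          power = seq(0.07, 0.12, length.out = 6))
  met2 <- tibble::tibble(individual = rep(c("a", "b"), each = 3),
                         speed = rep(c(5.3, 6.6, 7.1), 2),
                         power = seq(0.9, 1.4, length.out = 6))
  out2 <- efficiency_individual_pairs(mech2, met2)
  # brute-force double loop over records of the same individual
  brute <- 0
  dups_mech <- integer(0)
  for (i in seq_len(nrow(mech2))) {
    for (j in seq_len(nrow(met2))) {
      if (mech2$individual[i] == met2$individual[j] &&
          abs(mech2$speed[i] - met2$speed[j]) <= 0.5) {
        brute <- brute + 1
        dups_mech <- c(dups_mech, i)
      }
    }
  }
  expect_equal(nrow(out2$pairs), brute)
  expect_equal(out2$n_mech_duplicated, sum(table(dups_mech) > 1))
  # per-bat-per-bin summaries carry medians and ranges
  expect_true(all(c("efficiency_median", "efficiency_min", "efficiency_max")
                  %in% names(out2$summary)))
  # disjoint speeds produce an empty result with a notice
  expect_message(
    empty <- efficiency_individual_pairs(
      tibble::tibble(individual = "a", speed = 3, power = 0.1),
      tibble::tibble(individual = "a", speed = 9, power = 1)),
    "no within-individual")
  expect_equal(nrow(empty$pairs), 0)
})

test_that("paired efficiencies rise with speed on study-like synthetic data", {
  hits <- withr::with_seed(71, {
    vapply(1:20, function(i) {
      n <- 14
      ind <- rep(c("a", "b", "c", "d"), length.out = n)
      u1 <- runif(n, 5, 9)
      u2 <- pmin(pmax(u1 + runif(n, -0.4, 0.4), 4.5), 9.5)
      mech <- tibble::tibble(individual = ind, speed = u1,
                             power = predict(mech_curve(), u1) * rnorm(n, 1, 0.05))
      met <- tibble::tibble(individual = ind, speed = u2,
                            power = predict(met_curve(), u2) * rnorm(n, 1, 0.05))
      g <- glance(efficiency_individual_pairs(mech, met))
      g$r > 0 && g$r_squared > 0.2
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("muscle efficiency removes basal costs under both conventions", {
  expect_equal(muscle_efficiency(1.0, 0.08, 0.092), 1.1 * 0.092 / 0.92,
               tolerance = 1e-12)
  expect_lt(abs(muscle_efficiency(1.0, 0.08, 0.092) - 0.11), 1e-3)
  # with no basal cost and no overhead it reduces to the whole-animal ratio
  expect_equal(muscle_efficiency(1.0, 0, 0.092, overhead = 1), 0.092)
  # the strict algebraic inverse is slightly larger
  expect_gt(muscle_efficiency(1.0, 0.08, 0.092, "strict_inverse"),
            muscle_efficiency(1.0, 0.08, 0.092) - 1e-12)
  # muscle efficiency always exceeds whole-animal efficiency when bmr > 0
  expect_gt(muscle_efficiency(1.0, 0.08, 0.092), 0.092 / 1.0)
  expect_error(muscle_efficiency(0.07, 0.08, 0.01),
               class = "flightpower_invalid_input")
})

test_that("fixed-efficiency predictions underestimate measured metabolic power as expected", {
  met <- tibble::tibble(speed = 6, power = 1.0)
  flat_mech <- function(U) rep(0.092, length(U))
  out <- underestimation_stats(met, flat_mech, bmr = 0.08)
  expect_equal(out$predicted, 0.528, tolerance = 1e-12)
  expect_equal(out$underestimate_pct, 47.2, tolerance = 1e-6)
  # measured equal to predicted gives zero underestimate
  met0 <- tibble::tibble(speed = 6, power = 0.528)
  expect_equal(underestimation_stats(met0, flat_mech, 0.08)$underestimate_pct,
               0, tolerance = 1e-9)
  # raising the assumed efficiency lowers predictions, raising the deficit
  u23 <- underestimation_stats(met, flat_mech, 0.08, efficiency = 0.23)
  u40 <- underestimation_stats(met, flat_mech, 0.08, efficiency = 0.40)
  expect_gt(u40$underestimate_pct, u23$underestimate_pct)
  expect_equal(attr(u23, "summary")$mean_pct, u23$underestimate_pct[1])
})

test_that("all four estimators agree on noiseless data from a single curve pair", {
  speeds <- 5:9
  ind <- c("a", "b")
  mech <- tidyr::expand_grid(individual = ind, speed = as.numeric(speeds)) %>%
    dplyr::mutate(power = predict(mech_curve(), speed))
  met <- mech %>% dplyr::mutate(power = predict(met_curve(), speed))
  truth <- predict(mech_curve(), speeds) / predict(met_curve(), speeds)

  e1 <- efficiency_mean(mech, met)
  e2 <- efficiency_median_vonbusse(mech, met)
  f_mech <- suppressMessages(fit_power_curve(mech, k3_value = 0.0297))
  f_met <- suppressMessages(fit_power_curve(met, k3_value = 0.490))
  e3 <- efficiency_model_ratio(f_mech, f_met, speeds)
  e4 <- efficiency_individual_pairs(mech, met, tolerance = 0.4)
  e4_by_speed <- e4$pairs %>% dplyr::group_by(speed) %>%
    dplyr::summarise(eff = mean(efficiency))

  expect_equal(e1$efficiency, truth, tolerance = 1e-9)
  expect_equal(e2$efficiency, truth, tolerance = 1e-9)
  expect_equal(e3$efficiency, truth, tolerance = 0.01)
  expect_equal(e4_by_speed$eff, truth, tolerance = 1e-9)
})
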