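# U-shaped power-curve fitting, speed normalization and model comparison.

test_that("speed normalization follows the one-sixth weight rule", {
  expect_equal(normalize_speed(6, 1, 1), 6)
  expect_equal(normalize_speed(6, 1.1, 1), 6 * 1.1^(-1 / 6), tolerance = 1e-12)
  expect_lt(abs(normalize_speed(6, 1.1, 1) - 5.906), 1e-3)
  # heavier individual -> smaller normalized speed at fixed airspeed
  expect_true(normalize_speed(6, 1.2, 1) < normalize_speed(6, 0.8, 1))
})

test_that("noiseless single-individual data with pinned k3 recover k1 and k2 exactly", {
  truth <- mech_curve()
  speeds <- seq(5, 9, by = 0.5)
  recs <- tibble::tibble(individual = "a", speed = speeds,
                         power = predict(truth, speeds))
  fit <- suppressMessages(fit_power_curve(recs, k3 = "fixed",
                                          k3_value = 0.0297))
  expect_equal(fit$k1, 9.21e-5, tolerance = 1e-6)
  expect_equal(fit$k2, 0.176, tolerance = 1e-6)
  # published curves evaluate as frozen regression constants
  expect_equal(predict(mech_curve(), 6),
               9.21e-5 * 216 + 0.176 / 6 + 0.0297, tolerance = 1e-12)
  expect_equal(predict(met_curve_weight(), 7),
               4.11e-3 * 343 + 28.6 / 7 + 5.90, tolerance = 1e-12)
})

test_that("a mixed fit at the study's data scale recovers the generating coefficients", {
  recs <- simulate_power_records(k1 = 9.21e-5, k2 = 0.176, k3 = 0.0297,
                                 n_individuals = 4,
                                 flights_per_individual = 12,
                                 speed_range = c(4, 9), noise_sd = 0.005,
                                 ranef_sd = 0.004, power_type = "mech",
                                 seed = 21)
  fit <- fit_power_curve(recs, k3 = "fixed", u_mp_prior = 5)
  expect_lt(abs(fit$k1 / 9.21e-5 - 1), 0.15)
  expect_lt(abs(fit$k2 / 0.176 - 1), 0.15)
  expect_gt(fit$random_intercept_sd, 0)
  # pinned constant equals half the binned mean power around the prior
  in_bin <- abs(recs$speed - 5) <= 0.5
  expect_equal(fit$k3, 0.5 * mean(recs$power[in_bin]), tolerance = 1e-12)
})

test_that("degenerate designs raise identifiability errors", {
  same <- tibble::tibble(individual = "a", speed = rep(6, 8), power = 1)
  expect_error(fit_power_curve(same), class = "flightpower_data_error")
  few <- tibble::tibble(individual = "a", speed = c(5, 6), power = c(1, 1))
  expect_error(fit_power_curve(few), class = "flightpower_data_error")
})

test_that("the curve beats a line on U-shaped data and not on linear data", {
  u_shaped <- simulate_power_records(n_individuals = 6,
                                     flights_per_individual = 8,
                                     speed_range = c(2.5, 10),
                                     noise_sd = 0.03, ranef_sd = 0.03,
                                     seed = 31)
  cmp_u <- suppressWarnings(compare_to_linear(u_shaped, u_mp_prior = 6.9))
  expect_lt(cmp_u$p_value, 0.001)
  expect_equal(cmp_u$preferred, "curve")
  expect_false(cmp_u$nested)

  lin <- withr::with_seed(32, {
    n <- 48
    ind <- rep(sprintf("b%d", 1:6), each = 8)
    sp <- runif(n, 4, 9)
    tibble::tibble(individual = ind, speed = sp,
                   power = 0.2 + 0.1 * sp +
                     rep(rnorm(6, 0, 0.03), each = 8) + rnorm(n, 0, 0.05))
  })
  cmp_l <- suppressWarnings(compare_to_linear(lin, u_mp_prior = 6.5))
  expect_gt(cmp_l$p_value, 0.05)
})

test_that("identical log-likelihoods give a zero likelihood ratio", {
  recs <- simulate_power_records(seed = 33)
  fit <- fit_power_curve(recs, u_mp_prior = 6.9)
  cmp <- suppressWarnings(compare_to_linear(recs, u_mp_prior = 6.9,
                                            curve_fit = fit))
  # self-consistency of the statistic: lr = 2 * (ll_curve - ll_linear)
  expect_equal(cmp$lr, 2 * (fit$loglik - (fit$loglik - cmp$lr / 2)))
})

test_that("specific power divides by weight or lift with guards", {
  out <- specific_power(tibble::tibble(power = 0.65, body_weight = 0.0915),
                        "weight")
  expect_lt(abs(out$specific_power - 7.10), 0.005)
  expect_equal(specific_power(tibble::tibble(power = 2, body_weight = 1),
                              "weight")$specific_power, 2)
  half <- specific_power(tibble::tibble(power = 2, body_weight = c(1, 2)),
                         "weight")
  expect_equal(half$specific_power, c(2, 1))
  expect_error(specific_power(tibble::tibble(power = 1, body_weight = 1),
                              "lift"),
               class = "flightpower_data_error")
})

test_that("fitted curves expose analytic characteristic speeds and tidy output", {
  recs <- simulate_power_records(seed = 41)
  fit <- fit_power_curve(recs, u_mp_prior = 6.9)
  expect_equal(minimum_power_speed(fit),
               (fit$k2 / (3 * fit$k1))^0.25, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$term, c("k1", "k2", "k3"))
  gl <- glance(fit)
  expect_equal(gl$n_individuals, 8)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("speed normalization tightens pooled fits under mass variation", {
  wins <- withr::with_seed(51, {
    vapply(1:25, function(i) {
      n_ind <- 6; per <- 8
      w <- rnorm(n_ind, 0.09, 0.018) # ~20% weight variation
      w_ref <- mean(w)
      ind <- rep(seq_len(n_ind), each = per)
      u <- runif(n_ind * per, 4, 9)
      # each individual flies its own curve, stretched by the 1/6 rule
      u_star_true <- u * (w_ref / w[ind])^(1 / 6)
      power <- predict(met_curve(), pmax(u_star_true, 0.1)) +
        rnorm(n_ind * per, 0, 0.03)
      d <- tibble::tibble(individual = sprintf("i%d", ind), u = u,
                          u_star = normalize_speed(u, w[ind], w_ref),
                          power = power)
      rss <- function(speed_col) {
        dd <- dplyr::mutate(d, speed = .data[[speed_col]])
        f <- suppressMessages(fit_power_curve(dd, k3 = "free"))
        f$sigma
      }
      rss("u_star") < rss("u")
    }, logical(1))
  })
  expect_gte(mean(wins), 0.8)
})

test_that("metabolic curves fitted from study-like data are shallower than mechanical ones", {
  mech <- simulate_power_records(k1 = 9.21e-5, k2 = 0.176, k3 = 0.0297,
                                 n_individuals = 4,
                                 flights_per_individual = 12,
                                 noise_sd = 0.003, ranef_sd = 0.002,
                                 power_type = "mech", seed = 61)
  met <- simulate_power_records(noise_sd = 0.05, ranef_sd = 0.03, seed = 62)
  f_mech <- fit_power_curve(mech, k3 = "fixed", u_mp_prior = 5)
  f_met <- fit_power_curve(met, k3 = "fixed", u_mp_prior = 6.9)
  expect_gt(f_met$k2 / f_mech$k2, 1)
})
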