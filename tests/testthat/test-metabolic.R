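# Bicarbonate washout metabolics: fits, flight VCO2, fuel factors, filters.

test_that("washout fit recovers a noiseless exponential essentially exactly", {
  tt <- 0:600
  trace <- tibble::tibble(time_s = tt,
                          enrichment_ape = 20 * exp(-0.004 * tt),
                          co2_ml_min = 0.5, phase = "washout_pre")
  fit <- fit_washout(trace, "washout_pre")
  expect_equal(fit$amplitude, 20, tolerance = 1e-8)
  expect_equal(fit$decay_rate, 0.004, tolerance = 1e-8)
})

test_that("washout decay rate is recovered within 3% under 2% multiplicative noise", {
  errs <- withr::with_seed(101, {
    vapply(1:500, function(i) {
      tt <- seq(0, 299, length.out = 300)
      e <- 20 * exp(-0.004 * tt) * (1 + rnorm(300, 0, 0.02))
      tr <- tibble::tibble(time_s = tt, enrichment_ape = e,
                           co2_ml_min = 0.5, phase = "washout_pre")
      abs(fit_washout(tr, "washout_pre")$decay_rate / 0.004 - 1)
    }, numeric(1))
  })
  expect_lt(median(errs), 0.03)
})

test_that("degenerate washout traces raise classed fit errors", {
  tt <- 0:100
  flat <- tibble::tibble(time_s = tt, enrichment_ape = 5,
                         co2_ml_min = 0.5, phase = "washout_pre")
  expect_error(fit_washout(flat, "washout_pre"),
               class = "flightpower_fit_error")
  rising <- tibble::tibble(time_s = tt, enrichment_ape = 5 + 0.01 * tt,
                           co2_ml_min = 0.5, phase = "washout_pre")
  expect_error(fit_washout(rising, "washout_pre"),
               class = "flightpower_fit_error")
  short <- tibble::tibble(time_s = 1:5, enrichment_ape = exp(-(1:5)),
                          co2_ml_min = 0.5, phase = "washout_pre")
  expect_error(fit_washout(short, "washout_pre"),
               class = "flightpower_data_error")
})

test_that("flight VCO2 inverts the single-pool forward model", {
  # noiseless: near-exact recovery of the 3x resting step
  sim <- simulate_washout_trace(resting_vco2 = 1, flight_vco2 = 3,
                                flight_duration = 60, seed = 1)
  est <- flight_vco2(sim$trace, sim$event)
  expect_rel_equal(est$vco2_flight, 3, 1e-6)
  expect_rel_equal(est$vco2_rest, 1, 1e-6)
  # with enrichment noise the rate is still within 5%
  simn <- simulate_washout_trace(resting_vco2 = 1, flight_vco2 = 3,
                                 flight_duration = 60, noise_sd = 0.01,
                                 seed = 2)
  estn <- flight_vco2(simn$trace, simn$event)
  expect_rel_equal(estn$vco2_flight, 3, 0.05)
})

test_that("a trial spent entirely landed returns the resting rate", {
  sim <- simulate_washout_trace(flight_duration = 60,
                                landings = data.frame(start = 0, end = 60),
                                seed = 1)
  est <- flight_vco2(sim$trace, sim$event)
  expect_equal(est$flight_fraction, 0)
  expect_rel_equal(est$vco2_flight, est$vco2_rest, 1e-9)
})

test_that("halving the airborne fraction doubles the inferred excess rate", {
  sim <- simulate_washout_trace(resting_vco2 = 1, flight_vco2 = 3,
                                flight_duration = 80, seed = 3)
  pre <- fit_washout(sim$trace, "washout_pre")
  post <- fit_washout(sim$trace, "washout_post")
  full <- flight_event(sim$event$start, sim$event$end)
  halved <- flight_event(sim$event$start, sim$event$end,
                         landings = data.frame(start = sim$event$start,
                                               end = sim$event$start + 40))
  e_full <- flight_vco2(sim$trace, full, pre_fit = pre, post_fit = post)
  e_half <- flight_vco2(sim$trace, halved, pre_fit = pre, post_fit = post)
  excess_full <- e_full$vco2_flight - e_full$vco2_rest
  excess_half <- e_half$vco2_flight - e_half$vco2_rest
  expect_rel_equal(excess_half / excess_full, 2, 1e-9)
})

test_that("CO2-to-power conversion uses the published fuel factors", {
  expect_rel_equal(power_from_vco2(2.84, fuel_model("glycogen")), 1.0, 0.002)
  expect_equal(power_from_vco2(0, fuel_model("glycogen")), 0)
  v <- c(1.2, 2.5, 3.1)
  ratio <- power_from_vco2(v, "mixed") / power_from_vco2(v, "glycogen")
  expect_equal(ratio, rep(23.7 / 21.1, 3), tolerance = 1e-12)
})

test_that("basal metabolic rate conversion matches the oxyjoule equivalent", {
  expect_equal(bmr_from_respirometry(0.239), 0.239 * 20.1 / 60,
               tolerance = 1e-12)
  expect_lt(abs(bmr_from_respirometry(0.239) - 0.080), 5e-4)
  expect_equal(bmr_from_respirometry(0), 0)
  expect_warning(bmr_from_respirometry(0.24, temperature_c = 20),
                 "thermoneutrality")
  # a small synthetic cohort targeted at 0.08 W lands within one s.e.
  vo2 <- withr::with_seed(5, rnorm(10, 0.239, 0.02))
  bmrs <- bmr_from_respirometry(vo2)
  se <- sd(bmrs) / sqrt(10)
  expect_lt(abs(mean(bmrs) - 0.08), se + 1e-9)
})

test_that("flight filters apply the airborne-fraction, Z-score and individual rules", {
  base <- tibble::tibble(
    individual = rep("a", 6), speed = rep(6, 6),
    p_met = c(1, 1, 1, 1, 1, 1),
    flight_fraction = c(0.59, 0.60, 0.9, 0.9, 0.9, 0.9)
  )
  out <- filter_flights(base)
  expect_equal(nrow(out), 5) # the 0.59 flight is dropped, 0.60 retained
  expect_true(all(out$flight_fraction >= 0.6))

  # worked Z-score cases (population sd): {1,1,1,2} -> Z = 1.73 retained;
  # {1,1,1,1,3} -> Z = 2.0 retained (only strictly exceeding 2 is dropped)
  g1 <- tibble::tibble(individual = rep("a", 4), speed = 6,
                       p_met = c(1, 1, 1, 2), flight_fraction = 0.9)
  o1 <- filter_flights(g1)
  expect_equal(nrow(o1), 4)
  expect_equal(max(o1$z_score), 1.732051, tolerance = 1e-6)
  g2 <- tibble::tibble(individual = rep("a", 5), speed = 6,
                       p_met = c(1, 1, 1, 1, 3), flight_fraction = 0.9)
  o2 <- filter_flights(g2)
  expect_equal(nrow(o2), 5)
  expect_equal(max(o2$z_score), 2, tolerance = 1e-9)
  # a clear outlier is dropped
  g3 <- tibble::tibble(individual = rep("a", 6), speed = 6,
                       p_met = c(1, 1.1, 0.9, 1, 1, 5), flight_fraction = 0.9)
  o3 <- filter_flights(g3)
  expect_equal(nrow(o3), 5)
  expect_true(all(o3$p_met < 5))
  expect_true(any(grepl("outlier", attr(o3, "drop_log")$reason)))
})

test_that("individuals need more than three surviving flights", {
  recs <- tibble::tibble(
    individual = rep(c("a", "b"), c(3, 4)),
    speed = c(5, 6, 7, 5, 6, 7, 8),
    p_met = 1, flight_fraction = 0.9
  )
  out <- filter_flights(recs)
  expect_equal(unique(out$individual), "b")
  expect_equal(nrow(out), 4)
  # singleton speed groups have undefined Z and are retained
  expect_equal(out$z_score, rep(0, 4))
})

test_that("filters are order-stable away from the rule boundaries", {
  recs <- withr::with_seed(9, tibble::tibble(
    individual = rep(c("a", "b", "c"), each = 6),
    speed = rep(c(5, 6, 7, 8, 5.4, 6.6), 3),
    p_met = rnorm(18, 1, 0.05),
    flight_fraction = runif(18, 0.65, 1)
  ))
  out1 <- filter_flights(recs)
  out2 <- filter_flights(dplyr::arrange(recs, speed))
  expect_equal(dplyr::arrange(out1, individual, speed)$p_met,
               dplyr::arrange(out2, individual, speed)$p_met)
})
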