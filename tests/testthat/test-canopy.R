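make_sensor_records <- function(times, ppfd) {
  data.frame(timestamp = as.POSIXct(times, tz = "UTC"), ppfd = ppfd)
}

test_that("daily means respect the half-open midday window", {
  r <- make_sensor_records(c("2015-05-20 09:59:00", "2015-05-20 10:00:00",
                             "2015-05-20 13:59:59", "2015-05-20 14:00:00",
                             "2015-05-21 09:30:00"),
                           c(999, 100, 300, 999, 50))
  dm <- daily_means(r)
  expect_equal(nrow(dm), 1)          # day 141 only; day with no in-window
  expect_equal(dm$mean_ppfd, 200)    # records is omitted and counted
  expect_equal(dm$n_obs, 2)
  expect_equal(attr(dm, "n_days_dropped"), 1)
  none <- daily_means(make_sensor_records("2015-05-20 09:59:00", 10))
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_days_dropped"), 1)
})

test_that("spline smooth tracks a noise-free decline; derivative matches
          finite differences", {
  sc <- season_scenario(sensor_sdlog = 0, seed = 1)
  sim <- simulate_season(sc)
  sm <- fit_canopy_smooth(sim$sensor)
  truth <- season_trajectory(sc, sm$day, "fenced")
  interior <- sm$day > 110 & sm$day < 180
  expect_true(all(abs(sm$fitted[interior] - truth[interior]) /
                    truth[interior] < 0.02))
  # oracle: finite differences of fitted values through the predict path
  # (checks the basis/coefficient derivative against the fitted curve)
  h <- 1e-3
  f0 <- mgcv::predict.gam(sm$gam, data.frame(day_of_year = sm$day))
  fp <- mgcv::predict.gam(sm$gam, data.frame(day_of_year = sm$day + h))
  fm <- mgcv::predict.gam(sm$gam, data.frame(day_of_year = sm$day - h))
  expect_true(all(abs(sm$deriv - (fp - fm) / (2 * h)) < 1e-8))
  expect_true(all(abs(sm$deriv - (fp - f0) / h) < 1e-3))
  expect_error(fit_canopy_smooth(sim$sensor[1:10, ]), "distinct days")
})

test_that("closure scan handles constant, linear and no-plateau series", {
  set.seed(3)
  flat <- data.frame(day_of_year = 100:190,
                     mean_ppfd = 50 + rnorm(91, 0, 0.5))
  sm <- fit_canopy_smooth(flat)
  expect_true(all(sm$deriv_lo <= 0 & sm$deriv_hi >= 0))
  cd <- closure_day(sm)
  expect_true(is.na(cd$day))
  expect_equal(cd$reason, "no_decline")
  # strictly linear decline: slope significantly negative throughout
  lin <- data.frame(day_of_year = 100:190,
                    mean_ppfd = 200 - 1.5 * (100:190) / 1 +
                      rnorm(91, 0, 0.4))
  cd2 <- closure_day(fit_canopy_smooth(lin))
  expect_true(is.na(cd2$day))
  expect_equal(cd2$reason, "no_plateau")
})

test_that("closure day is invariant to rescaling and converges with noise",
          {
  sim <- simulate_season(season_scenario(seed = 3))
  d1 <- closure_day(fit_canopy_smooth(sim$sensor))$day
  scaled <- sim$sensor
  scaled$mean_ppfd <- scaled$mean_ppfd * 1000   # unit change
  expect_equal(closure_day(fit_canopy_smooth(scaled))$day, d1)
  # detection tightens as sensor noise shrinks (3 noise levels)
  spread <- sapply(c(0.25, 0.1, 0.02), function(sdl) {
    days <- sapply(1:15, function(s) closure_day(fit_canopy_smooth(
      simulate_season(season_scenario(sensor_sdlog = sdl,
                                      seed = s))$sensor))$day)
    stats::sd(days, na.rm = TRUE)
  })
  expect_true(spread[3] <= spread[1] + 1e-9)
  expect_lt(spread[3], 1)
})

test_that("likelihood ratio test behaves on identical and nested models", {
  sim <- simulate_season(season_scenario(seed = 8))
  fit <- fit_ppfd_lmm(sim$plants)
  full <- fit$models$interaction
  lt <- lr_test(full, full)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p, 1)
  expect_error(lr_test(fit$models$time, fit$models$interaction),
               "more parameters")
  # term table reports the sequential-addition df pairs
  expect_equal(fit$term_table$df, c("(5,6)", "(6,7)", "(7,8)", "(8,9)"))
})

test_that("LR statistic is invariant to recoding the fencing indicator", {
  sim <- simulate_season(season_scenario(seed = 12))
  f1 <- fit_ppfd_lmm(sim$plants)
  relab <- sim$plants
  relab$treatment <- ifelse(relab$treatment == "fenced", "unfenced",
                            "fenced")
  f2 <- fit_ppfd_lmm(relab)
  expect_equal(f1$term_table$likelihood_ratio,
               f2$term_table$likelihood_ratio, tolerance = 1e-4)
})

test_that("heteroscedastic model nests the homoscedastic one", {
  for (seed in c(4, 21)) {
    sim <- simulate_season(season_scenario(seed = seed))
    het <- fit_ppfd_lmm(sim$plants, heteroscedastic = TRUE)
    hom <- fit_ppfd_lmm(sim$plants, heteroscedastic = FALSE)
    expect_gte(het$logLik, hom$logLik - 1e-6)
    expect_equal(het$n_params, hom$n_params + 2)  # two power exponents
  }
})

test_that("homoscedastic submodel agrees with an independent ML mixed fit",
          {
  sim <- simulate_season(season_scenario(seed = 6))
  hom <- fit_ppfd_lmm(sim$plants, heteroscedastic = FALSE)
  d <- data.frame(y = log(sim$plants$mean_ppfd),
                  dayc = sim$plants$day_of_year -
                    mean(sim$plants$day_of_year),
                  treatment = factor(sim$plants$treatment,
                                     levels = c("fenced", "unfenced")),
                  day_f = factor(sim$plants$day_of_year))
  oracle <- lme4::lmer(y ~ dayc + I(dayc^2) + treatment + dayc:treatment +
                         (1 | day_f), data = d, REML = FALSE)
  expect_equal(hom$logLik, as.numeric(stats::logLik(oracle)),
               tolerance = 1e-4)
})

test_that("original-scale treatment means recover known plateaus", {
  # all measurement days post-closure: trajectories are flat, which the
  # quadratic fixed-effect structure represents exactly
  sc <- season_scenario(noise_sdlog = 0.0001, sensor_sdlog = 0,
                        measurement_days = seq(156, 176, by = 2),
                        seed = 14)
  sim <- simulate_season(sc)
  fit <- fit_ppfd_lmm(sim$plants)
  pm <- treatment_means_original_scale(fit, 172)
  expect_equal(pm$mean_ppfd[pm$treatment == "fenced"],
               season_trajectory(sc, 172, "fenced"), tolerance = 0.02)
  expect_equal(pm$mean_ppfd[pm$treatment == "unfenced"],
               season_trajectory(sc, 172, "unfenced"), tolerance = 0.02)
  expect_error(treatment_means_original_scale(fit, 300), "extrapolate")
  # more plants, tighter SEs
  big <- simulate_season(season_scenario(
    plant_count = c(fenced = 300, unfenced = 300), seed = 14))
  small <- simulate_season(season_scenario(
    plant_count = c(fenced = 15, unfenced = 15), seed = 14))
  se_big <- treatment_means_original_scale(fit_ppfd_lmm(big$plants), 160)$se
  se_small <- treatment_means_original_scale(fit_ppfd_lmm(small$plants),
                                             160)$se
  expect_true(all(se_big < se_small))
})
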