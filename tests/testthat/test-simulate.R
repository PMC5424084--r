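test_that("simulated light curves hit the model exactly at zero noise", {
  tr <- list(a_max = 9.40, phi = 0.077, r_d = 0.52, theta = 0.9)
  c0 <- simulate_light_curve(tr, noise_sd = 0, seed = 1)
  expect_equal(c0$a_net[c0$ppfd == 0], -0.52)
  expect_equal(signif(c0$a_net[c0$ppfd == 200], 3), 7.87)
  # determinism: same seed, same bytes
  c1 <- simulate_light_curve(tr, noise_sd = 0.3, seed = 9)
  c2 <- simulate_light_curve(tr, noise_sd = 0.3, seed = 9)
  expect_identical(c1, c2)
  expect_false(identical(c1$a_net,
                         simulate_light_curve(tr, noise_sd = 0.3,
                                              seed = 10)$a_net))
})

test_that("simulated A/Ci curves follow the supply function and model", {
  tr <- list(v_cmax = 27.73, j_max = 43.49, r_day = 0.5)
  c0 <- simulate_aci_curve(tr, noise_sd = 0, seed = 1)
  expect_equal(nrow(c0), 11)
  expect_equal(c0$ci, 0.7 * default_co2_sequence() * 101.325 / 1000)
  # a step at ci = gamma_star would sit exactly at -r_day; the 50-ppm step
  # lands below gamma_star and its (negative) record is kept
  expect_true(any(c0$ci < 3.7))
  expect_true(all(is.finite(c0$a_net)))
  expect_equal(c0$a_net,
               as.numeric(fvcb_net(c0$ci, tr$v_cmax, tr$j_max, tr$r_day)))
  expect_identical(simulate_aci_curve(tr, seed = 4),
                   simulate_aci_curve(tr, seed = 4))
})

test_that("season simulation is deterministic and respects symmetry", {
  sc <- season_scenario(seed = 5)
  expect_identical(simulate_season(sc), simulate_season(sc))
  # equal treatments, zero noise: identical trajectories
  sc0 <- season_scenario(pre_closure_ppfd = c(fenced = 50, unfenced = 50),
                         post_closure_ppfd = c(fenced = 15, unfenced = 15),
                         plant_count = c(fenced = 5, unfenced = 5),
                         noise_sdlog = 0, sensor_sdlog = 0, seed = 2)
  sim <- simulate_season(sc0)
  d <- sim$plants
  for (day in unique(d$day_of_year)) {
    f <- unique(d$mean_ppfd[d$treatment == "fenced" & d$day_of_year == day])
    u <- unique(d$mean_ppfd[d$treatment == "unfenced" &
                              d$day_of_year == day])
    if (length(f) && length(u)) expect_equal(f, u)
  }
  # high steepness: the sensor trajectory is flat beyond the closure day
  sc1 <- season_scenario(decline_steepness = 3, sensor_sdlog = 0, seed = 2)
  tra <- season_trajectory(sc1, 153:190, "fenced")
  expect_true(all(abs(diff(tra)) < 1e-3))
})

test_that("plant-level sampling matches the declared count distribution", {
  sc <- season_scenario(plant_count = c(fenced = 2000, unfenced = 2000),
                        seed = 11)
  sim <- simulate_season(sc)
  n <- sim$plants$n_measurements
  expect_true(all(n >= 1 & n <= 16))
  expect_equal(mean(n), 5.95, tolerance = 0.05)
  # generated tables carry the schema the analysis functions consume
  expect_true(all(c("plant_id", "treatment", "day_of_year", "mean_ppfd",
                    "n_measurements") %in% names(sim$plants)))
  expect_true(all(sim$plants$mean_ppfd >= 0))
  expect_true(all(c("day_of_year", "mean_ppfd", "n_obs") %in%
                    names(sim$sensor)))
})

test_that("trait tables reduce to their cell means at zero variance", {
  sim <- simulate_trait_table(trait_means = c(fenced = 674, unfenced = 350),
                              n_individuals = 6, n_dates = 3,
                              sd_individual = 0, sd_date = 0, sd_resid = 0,
                              asat_cell_means = data.frame(
                                month = rep(c("May", "Jun"), each = 2),
                                treatment = rep(c("fenced", "unfenced"), 2),
                                mean = c(5, 5, 2, 4)),
                              n_per_cell = 3, asat_sd = 0, seed = 1)
  expect_true(all(sim$traits$value[sim$traits$treatment == "fenced"] == 674))
  expect_true(all(sim$traits$value[sim$traits$treatment == "unfenced"] ==
                    350))
  agg <- aggregate(asat ~ month + treatment, sim$asat, unique)
  expect_equal(agg$asat[agg$month == "Jun" & agg$treatment == "unfenced"], 4)
  # repeated measures spread individuals across dates
  sim2 <- simulate_trait_table(n_individuals = 4, n_dates = 4,
                               measurements_per_individual = 3, seed = 2)
  tab <- table(sim2$traits$plant_id)
  expect_true(all(tab == 3))
  per_ind_dates <- tapply(sim2$traits$date_id, sim2$traits$plant_id,
                          function(x) length(unique(x)))
  expect_true(all(per_ind_dates == 3))
})
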