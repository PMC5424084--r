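test_that("weighted group means use 1/SE weights as printed", {
  # {10, 20} with SEs {1, 4}: (10/1 + 20/4) / (1 + 1/4) = 12
  wm <- weighted_group_mean(c(10, 20), c(1, 4))
  expect_equal(wm$mean, 12)
  # equal SEs reduce to the arithmetic mean
  expect_equal(weighted_group_mean(c(3, 5, 10), c(2, 2, 2))$mean, 6)
  one <- weighted_group_mean(7.3, 0.9)
  expect_equal(one$mean, 7.3)
  expect_equal(one$se, 0.9)
  expect_error(weighted_group_mean(c(1, 2), c(1, 0)), "> 0")
  # inverse-variance alternative is distinct
  expect_equal(weighted_group_mean(c(10, 20), c(1, 4),
                                   scheme = "inverse_var")$mean,
               (10 + 20 / 16) / (1 + 1 / 16))
})

test_that("percent change is exact, reciprocal and rounds half away from
          zero", {
  expect_equal(percent_change(9.40, 6.26)$percent_rounded, 50L)
  expect_equal(percent_change(350, 674)$percent_rounded, -48L)
  expect_equal(percent_change(5, 5)$percent_rounded, 0L)
  expect_error(percent_change(1, 0), "zero")
  # reciprocal identity holds exactly on unrounded values
  for (pair in list(c(9.40, 6.26), c(350, 674), c(15.63, 52.03))) {
    p1 <- percent_change(pair[1], pair[2])$percent
    p2 <- percent_change(pair[2], pair[1])$percent
    expect_equal((1 + p1 / 100) * (1 + p2 / 100), 1)
  }
  # half-away-from-zero at the .5 boundary, both signs
  expect_equal(percent_change(120.5, 100)$percent_rounded, 21L)
  expect_equal(percent_change(79.5, 100)$percent_rounded, -21L)
})

test_that("seasonal ANOVA accounts its residual df and flags transforms", {
  sim <- simulate_trait_table(
    trait_means = c(fenced = 1, unfenced = 1),
    asat_cell_means = expand.grid(month = month.abb[c(1, 4:11, 12)],
                                  treatment = c("fenced", "unfenced"),
                                  KEEP.OUT.ATTRS = FALSE) |>
      transform(mean = 5),
    n_per_cell = 12, asat_sd = 0.5, seed = 3)
  names(sim$asat)[names(sim$asat) == "asat"] <- "asat"
  fit <- asat_anova(sim$asat, transform = "none")
  # 240 observations in a 10-month x 2-treatment cell-means model
  expect_equal(nrow(fit$data), 240)
  expect_equal(fit$residual_df, 240 - 20)
  expect_false(fit$log_transformed)
  # multiplicative errors trigger the log diagnostic
  skewed <- sim$asat
  set.seed(4)
  skewed$asat <- exp(rnorm(nrow(skewed), log(5), 0.8)) *
    ifelse(skewed$treatment == "fenced", 1, 3)
  fit2 <- asat_anova(skewed, transform = "auto")
  expect_true(fit2$log_transformed)
  expect_error(asat_anova(sim$asat[sim$asat$month == "Jan", ]), "months")
})

test_that("monthly contrasts use pooled variance and flag empty cells", {
  cell <- expand.grid(month = c("May", "Jun", "Jul"),
                      treatment = c("fenced", "unfenced"),
                      KEEP.OUT.ATTRS = FALSE)
  cell$mean <- ifelse(cell$month == "Jun" & cell$treatment == "unfenced",
                      8, 5)
  sim <- simulate_trait_table(asat_cell_means = cell, n_per_cell = 10,
                              asat_sd = 1, seed = 7)
  fit <- asat_anova(sim$asat, transform = "none")
  ct <- monthly_contrasts(fit)
  expect_equal(ct$df, rep(fit$residual_df, 3))
  jun <- ct[ct$month == "Jun", ]
  expect_lt(jun$p, 0.001)
  expect_gt(min(ct$p[ct$month != "Jun"]), 0.05)
  # independent oracle: multcomp glht on the same contrast
  newf <- expand.grid(treatment = factor(c("fenced", "unfenced"),
                                         levels = c("fenced", "unfenced")),
                      month = factor("Jun", levels = levels(fit$data$month)))
  x <- stats::model.matrix(~ treatment * month, newf)
  g <- multcomp::glht(fit$model, linfct = (x[2, ] - x[1, ]) |> t())
  s <- summary(g)
  expect_equal(jun$t, unname(s$test$tstat), tolerance = 1e-10)
  # a month missing one treatment is flagged, not tested
  drop <- sim$asat[!(sim$asat$month == "Jul" &
                       sim$asat$treatment == "fenced"), ]
  ct2 <- monthly_contrasts(asat_anova(drop, transform = "none"))
  expect_false(ct2$tested[ct2$month == "Jul"])
  expect_true(is.na(ct2$p[ct2$month == "Jul"]))
})

test_that("trait LRT chi-square equals 2 x delta log-likelihood", {
  sim <- simulate_trait_table(trait_means = c(fenced = 674, unfenced = 350),
                              n_individuals = 20, n_dates = 4,
                              measurements_per_individual = 2,
                              sd_individual = 30, sd_date = 15,
                              sd_resid = 60, seed = 5)
  cmp <- trait_lrt(sim$traits, trait = "SLA")
  ll_full <- as.numeric(stats::logLik(cmp$models$full))
  ll_red <- as.numeric(stats::logLik(cmp$models$reduced))
  expect_equal(cmp$chi_sq, 2 * (ll_full - ll_red), tolerance = 1e-6)
  expect_equal(cmp$df, 1)
  expect_lt(cmp$p, 0.001)
  # group means: fenced above unfenced by construction
  m <- cmp$means
  expect_gt(m$mean[m$treatment == "fenced"],
            m$mean[m$treatment == "unfenced"])
})

test_that("equal weights reproduce the unweighted trait LRT", {
  sim <- simulate_trait_table(trait_means = c(fenced = 10, unfenced = 8),
                              n_individuals = 15, sd_resid = 1.5, seed = 9)
  d <- sim$traits
  d$se <- 2                      # constant precision
  unw <- trait_lrt(d, random_effects = "date", weights = "none")
  wtd <- trait_lrt(d, random_effects = "date", weights = "inverse_se")
  expect_equal(unw$chi_sq, wtd$chi_sq, tolerance = 1e-6)
  expect_equal(unw$p, wtd$p, tolerance = 1e-6)
})

test_that("detectable trait effects are flagged significant with power", {
  hits <- sapply(1:20, function(s) {
    sim <- simulate_trait_table(
      trait_means = c(fenced = 674, unfenced = 350),
      n_individuals = 50, n_dates = 4, measurements_per_individual = 1,
      sd_individual = 0, sd_date = 40, sd_resid = 120, seed = s)
    cmp <- trait_lrt(sim$traits)
    pc <- percent_change(
      cmp$means$mean[cmp$means$treatment == "unfenced"],
      cmp$means$mean[cmp$means$treatment == "fenced"])
    c(sig = cmp$p < 0.05, pct = pc$percent)
  })
  expect_gte(mean(hits["sig", ]), 0.95)
  # recovered percent change centres on the generating -48 %
  expect_equal(mean(hits["pct", ]), -48, tolerance = 0.05)
})

test_that("trait panel report has the full nine-trait shape and is pure", {
  sim <- simulate_trait_table(trait_means = c(fenced = 674, unfenced = 350),
                              n_individuals = 12, sd_resid = 40, seed = 2)
  sla <- trait_lrt(sim$traits, trait = "SLA")
  panel <- list(Alliaria = list(SLA = sla),
                Trillium = list(SLA = trait_lrt(sim$traits, trait = "SLA")))
  rep1 <- table2_report(panel)
  rep2 <- table2_report(panel)
  expect_identical(rep1, rep2)
  expect_equal(nrow(rep1), 18)   # 9 traits x 2 species
  expect_equal(sum(rep1$available), 2)
  # unavailable panels (e.g. single-treatment A/Ci) carry NA tests
  expect_true(all(is.na(rep1$chi_sq[!rep1$available])))
})
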