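#' Default PPFD step sequence for simulated light-response curves
#'
#' Eleven steps from 0 to 1500 umol photons m-2 s-1, the span of a standard
#' portable-system light-response routine.
#' @return Numeric vector of PPFD levels.
#' @export
default_ppfd_levels <- function() {
  c(0, 25, 50, 100, 200, 300, 500, 800, 1100, 1300, 1500)
}

#' Standard 11-step chamber CO2 sequence for A/Ci curves
#'
#' The conventional down-then-up routine with triplicate 400 umol mol-1
#' stability checks: 400, 300, 200, 100, 50, 400, 400, 600, 800, 1000, 1500.
#' @return Numeric vector of reference-chamber CO2 mole fractions
#'   (umol mol-1).
#' @export
default_co2_sequence <- function() {
  c(400, 300, 200, 100, 50, 400, 400, 600, 800, 1000, 1500)
}

#' Simulate a light-response curve with known truth
#'
#' Evaluates the NRH model at each PPFD level and adds iid Gaussian
#' instrument noise. Deterministic given `seed`.
#'
#' @param truth Named list/vector with `a_max`, `phi`, `r_d`, `theta`
#'   (ground-truth NRH parameters; see [nrh_anet()] for units).
#' @param ppfd_levels PPFD steps, umol photons m-2 s-1, within `[0, 2000]`.
#' @param noise_sd Gaussian sd of instrument noise on `a_net`,
#'   umol CO2 m-2 s-1 (default 0.2, typical chamber stability).
#' @param seed Integer RNG seed.
#' @param plant_id Identifier stamped on the records.
#' @return Data frame with `plant_id`, `curve_id`, `ppfd`, `a_net` and
#'   attribute `truth`.
#' @export
simulate_light_curve <- function(truth, ppfd_levels = default_ppfd_levels(),
                                 noise_sd = 0.2, seed = 1L,
                                 plant_id = "sim1") {
  truth <- as.list(truth)
  stopifnot(truth$a_max > 0, truth$phi > 0, truth$phi <= 0.125,
            truth$r_d >= 0, truth$r_d < truth$a_max,
            truth$theta >= 0, truth$theta < 1,
            all(ppfd_levels >= 0), all(ppfd_levels <= 2000), noise_sd >= 0)
  mu <- nrh_anet(ppfd_levels, truth$a_max, truth$phi, truth$r_d, truth$theta)
  eps <- .with_seed(seed, stats::rnorm(length(ppfd_levels), 0, noise_sd))
  out <- data.frame(plant_id = plant_id,
                    curve_id = paste0(plant_id, "_light_001"),
                    ppfd = ppfd_levels, a_net = mu + eps)
  attr(out, "truth") <- truth
  out
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an A/Ci curve with known truth
#'
#' Chamber CO2 is mapped to intercellular CO2 through a linear supply
#' function `ci_umol_mol = k_supply * co2_ref` (stomata keep Ci a roughly
#' constant fraction of ambient), then converted to partial pressure via
#' `ci_Pa = ci_umol_mol * pressure / 1000`. Net assimilation is
#' [fvcb_net()] plus Gaussian noise; steps with `ci <= gamma_star` are kept
#' (negative net rates are legitimate data).
#'
#' @param truth Named list/vector with `v_cmax`, `j_max`, `r_day`.
#' @param constants A [kinetic_constants()] object.
#' @param co2_ref_sequence Chamber CO2 steps, umol mol-1.
#' @param k_supply Ci / chamber-CO2 ratio (default 0.7).
#' @param pressure Atmospheric pressure, kPa.
#' @param noise_sd Gaussian sd on `a_net`.
#' @param seed Integer RNG seed.
#' @param plant_id Identifier stamped on the records.
#' @return Data frame with `plant_id`, `curve_id`, `co2_ref`, `ci` (Pa),
#'   `a_net`; attribute `truth`.
#' @export
simulate_aci_curve <- function(truth, constants = kinetic_constants(),
                               co2_ref_sequence = default_co2_sequence(),
                               k_supply = 0.7, pressure = 101.325,
                               noise_sd = 0.2, seed = 1L, plant_id = "sim1") {
  truth <- as.list(truth)
  stopifnot(truth$v_cmax > 0, truth$j_max > 0, truth$r_day >= 0,
            k_supply > 0, k_supply <= 1, noise_sd >= 0)
  if (truth$j_max <= truth$v_cmax) {
    warning("j_max <= v_cmax is atypical for C3 leaves")
  }
  ci <- k_supply * co2_ref_sequence * pressure / 1000
  mu <- as.numeric(fvcb_net(ci, truth$v_cmax, truth$j_max, truth$r_day,
                            constants))
  eps <- .with_seed(seed, stats::rnorm(length(ci), 0, noise_sd))
  out <- data.frame(plant_id = plant_id,
                    curve_id = paste0(plant_id, "_aci_001"),
                    co2_ref = co2_ref_sequence, ci = ci, a_net = mu + eps)
  attr(out, "truth") <- truth
  out
}

#' Season scenario for understory-light simulation
#'
#' Defines the conditions of a simulated growing season: per-treatment PPFD
#' before and after canopy closure, the logistic decline between them, the
#' sampling design (plants per treatment, measurement days, per-plant
#' measurement counts) and noise. Defaults mirror a fenced/unfenced
#' deer-exclosure season: the fenced understory declines from ~57 to ~16
#' umol photons m-2 s-1 with canopy closure around day 148, while the
#' unfenced understory stays near 52; 75 fenced and 110 unfenced plants are
#' measured on 11 days between mid-May and late June, with 1-16 measurements
#' per plant averaging about 5.95.
#'
#' The treatment trajectory is
#' `post + (pre - post) / (1 + exp(steepness * (day - midpoint)))` with
#' `midpoint = closure_day - 3 / steepness`, so the decline has effectively
#' finished (within ~5 % of the plateau) by `closure_day`.
#'
#' @param closure_day True day-of-year of plateau onset (canopy closure).
#' @param pre_closure_ppfd,post_closure_ppfd Named vectors
#'   (`fenced`, `unfenced`) of plateau PPFD levels; `post <= pre` per
#'   treatment.
#' @param decline_steepness Logistic rate (day-1).
#' @param plant_count Named integer vector of plants per treatment (>= 2).
#' @param measurement_days Days-of-year on which plants are measured.
#' @param mean_measurements Target mean of the truncated-geometric (1-16)
#'   per-plant measurement-count distribution.
#' @param noise_sdlog Lognormal sd of plant-mean PPFD around the treatment
#'   trajectory.
#' @param sensor_sdlog Lognormal sd of the fixed-sensor daily means.
#' @param sensor_days Days-of-year covered by the fixed sensor
#'   (April-July by default).
#' @param seed Integer RNG seed.
#' @return A list of class `season_scenario`.
#' @export
season_scenario <- function(closure_day = 148,
                            pre_closure_ppfd = c(fenced = 57.4,
                                                 unfenced = 52.03),
                            post_closure_ppfd = c(fenced = 15.63,
                                                  unfenced = 52.03),
                            decline_steepness = 0.5,
                            plant_count = c(fenced = 75, unfenced = 110),
                            measurement_days = seq(135, 175, by = 4),
                            mean_measurements = 5.95,
                            noise_sdlog = 0.6,
                            sensor_sdlog = 0.18,
                            sensor_days = 100:190,
                            seed = 1L) {
  stopifnot(all(c("fenced", "unfenced") %in% names(pre_closure_ppfd)),
            all(c("fenced", "unfenced") %in% names(post_closure_ppfd)),
            all(post_closure_ppfd <= pre_closure_ppfd + 1e-9),
            all(plant_count >= 2), decline_steepness > 0,
            noise_sdlog >= 0, sensor_sdlog >= 0)
  structure(list(closure_day = closure_day,
                 pre_closure_ppfd = pre_closure_ppfd,
                 post_closure_ppfd = post_closure_ppfd,
                 decline_steepness = decline_steepness,
                 plant_count = plant_count,
                 measurement_days = measurement_days,
                 mean_measurements = mean_measurements,
                 noise_sdlog = noise_sdlog,
                 sensor_sdlog = sensor_sdlog,
                 sensor_days = sensor_days,
                 seed = seed), class = "season_scenario")
}

#' Treatment PPFD trajectory of a season scenario
#'
#' @param scenario A [season_scenario()].
#' @param day Day(s) of year.
#' @param treatment `"fenced"` or `"unfenced"`.
#' @return Noise-free mean PPFD at `day`.
#' @export
season_trajectory <- function(scenario, day, treatment) {
  pre <- scenario$pre_closure_ppfd[[treatment]]
  post <- scenario$post_closure_ppfd[[treatment]]
  mid <- scenario$closure_day - 3 / scenario$decline_steepness
  post + (pre - post) / (1 + exp(scenario$decline_steepness * (day - mid)))
}

# truncated geometric on 1..16 with the requested mean
.truncgeom_probs <- function(mean_target, kmax = 16) {
  ks <- seq_len(kmax)
  mean_of <- function(q) sum(ks * q^(ks - 1)) / sum(q^(ks - 1))
  if (mean_target <= 1) return(c(1, rep(0, kmax - 1)))
  q <- stats::uniroot(function(q) mean_of(q) - mean_target,
                      c(1e-6, 1 - 1e-9))$root
  p <- q^(ks - 1)
  p / sum(p)
}

#' Simulate a growing season of understory light
#'
#' Generates (i) a fixed-sensor daily PPFD series that follows the fenced
#' treatment trajectory (the sensor sits inside the exclosure) with
#' lognormal day-to-day noise, and (ii) plant-level mean-PPFD records: each
#' plant is assigned a measurement day, a measurement count drawn from a
#' truncated geometric on 1-16 tuned to `mean_measurements`, and a mean PPFD
#' drawn lognormally around its treatment trajectory. Deterministic given
#' the scenario seed.
#'
#' @param scenario A [season_scenario()].
#' @return A list of class `season_sim`: `sensor` (data frame `day_of_year`,
#'   `mean_ppfd`, `n_obs`), `plants` (data frame `plant_id`, `treatment`,
#'   `day_of_year`, `mean_ppfd`, `n_measurements`) and `truth` (the
#'   scenario).
#' @export
simulate_season <- function(scenario = season_scenario()) {
  .with_seed(scenario$seed, {
    sensor <- data.frame(
      day_of_year = scenario$sensor_days,
      mean_ppfd = season_trajectory(scenario, scenario$sensor_days,
                                    "fenced") *
        exp(stats::rnorm(length(scenario$sensor_days), 0,
                         scenario$sensor_sdlog)),
      n_obs = 16L)

    probs <- .truncgeom_probs(scenario$mean_measurements)
    plants <- do.call(rbind, lapply(c("fenced", "unfenced"), function(tr) {
      n <- scenario$plant_count[[tr]]
      day <- sample(scenario$measurement_days, n, replace = TRUE)
      data.frame(
        plant_id = sprintf("%s_%03d", tr, seq_len(n)),
        treatment = tr,
        day_of_year = day,
        mean_ppfd = season_trajectory(scenario, day, tr) *
          exp(stats::rnorm(n, 0, scenario$noise_sdlog)),
        n_measurements = sample(seq_along(probs), n, replace = TRUE,
                                prob = probs))
    }))
    rownames(plants) <- NULL
    structure(list(sensor = sensor, plants = plants, truth = scenario),
              class = "season_sim")
  })
}

#' Simulate a leaf-trait table and spot-Asat records with known effects
#'
#' Each observation is grand mean + treatment effect + individual random
#' intercept + date random intercept + residual. The companion spot-Asat
#' table gets month-by-fencing cell means with the same error structure,
#' for exercising the seasonal ANOVA and monthly contrasts.
#'
#' @param trait_means Named vector (`fenced`, `unfenced`) of true trait cell
#'   means (e.g. SLA in cm2 g-1).
#' @param n_individuals Individuals per treatment.
#' @param n_dates Number of measurement dates.
#' @param measurements_per_individual Rows per individual (default 1: each
#'   individual measured once, on a cyclically assigned date; larger values
#'   spread each individual's repeated measurements across dates, making
#'   both variance components identifiable).
#' @param sd_individual,sd_date,sd_resid Standard deviations of the
#'   individual and date random intercepts and the residual (>= 0).
#' @param asat_cell_means Optional data frame (`month`, `treatment`, `mean`)
#'   of true Asat cell means; `NULL` skips the Asat table.
#' @param n_per_cell Asat observations per month-by-treatment cell.
#' @param asat_sd Residual sd of the Asat observations.
#' @param seed Integer RNG seed.
#' @return A list of class `trait_sim`: `traits` (data frame `plant_id`,
#'   `treatment`, `date_id`, `value`), `asat` (data frame `plant_id`,
#'   `treatment`, `month`, `asat`, or `NULL`) and `truth`.
#' @export
simulate_trait_table <- function(trait_means = c(fenced = 674,
                                                 unfenced = 350),
                                 n_individuals = 25, n_dates = 4,
                                 measurements_per_individual = 1,
                                 sd_individual = 0, sd_date = 0,
                                 sd_resid = 1,
                                 asat_cell_means = NULL, n_per_cell = 12,
                                 asat_sd = 1, seed = 1L) {
  stopifnot(all(c("fenced", "unfenced") %in% names(trait_means)),
            sd_individual >= 0, sd_date >= 0, sd_resid >= 0, asat_sd >= 0)
  .with_seed(seed, {
    date_re <- stats::rnorm(n_dates, 0, sd_date)
    m <- min(measurements_per_individual, n_dates)
    traits <- do.call(rbind, lapply(c("fenced", "unfenced"), function(tr) {
      ind_re <- stats::rnorm(n_individuals, 0, sd_individual)
      rows <- expand.grid(ind = seq_len(n_individuals), rep = seq_len(m))
      date_id <- 1 + (rows$ind + rows$rep - 2) %% n_dates
      data.frame(
        plant_id = sprintf("%s_i%03d", tr, rows$ind),
        treatment = tr,
        date_id = sprintf("d%02d", date_id),
        value = trait_means[[tr]] + ind_re[rows$ind] + date_re[date_id] +
          stats::rnorm(nrow(rows), 0, sd_resid))
    }))
    rownames(traits) <- NULL

    asat <- NULL
    if (!is.null(asat_cell_means)) {
      stopifnot(all(c("month", "treatment", "mean") %in%
                      names(asat_cell_means)))
      asat <- do.call(rbind, lapply(seq_len(nrow(asat_cell_means)),
                                    function(i) {
        cell <- asat_cell_means[i, ]
        data.frame(
          plant_id = sprintf("%s_%s_p%03d", cell$treatment, cell$month,
                             seq_len(n_per_cell)),
          treatment = cell$treatment,
          month = cell$month,
          asat = cell$mean + stats::rnorm(n_per_cell, 0, asat_sd))
      }))
      rownames(asat) <- NULL
    }
    structure(list(traits = traits, asat = asat,
                   truth = list(trait_means = trait_means,
                                sd_individual = sd_individual,
                                sd_date = sd_date, sd_resid = sd_resid,
                                asat_cell_means = asat_cell_means)),
              class = "trait_sim")
  })
}
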