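# Shared fixtures: random-but-reproducible ground truths and tiny CSV logs.

random_light_truth <- function(seed) {
  set.seed(seed)
  list(a_max = runif(1, 4, 10), phi = runif(1, 0.05, 0.09),
       r_d = runif(1, 0.1, 0.6), theta = runif(1, 0.5, 0.95))
}

random_aci_truth <- function(seed) {
  set.seed(seed)
  v <- runif(1, 15, 35)
  list(v_cmax = v, j_max = v * runif(1, 1.5, 1.9),
       r_day = runif(1, 0.2, 1))
}

# minimal well-formed gas-exchange log rows
example_log_df <- function() {
  data.frame(
    plant_id = c("p1", "p1", "p2"),
    species = c("Alliaria", "Alliaria", "Trillium"),
    life_stage = c("rosette", "rosette", "adult"),
    treatment = c("fenced", "fenced", "unfenced"),
    timestamp = c("2015-06-01 10:00:00", "2015-06-01 10:05:00",
                  "2015-06-01 11:00:00"),
    ppfd = c(0, 200.1234, 1500),
    a_net = c(-0.52, 7.8742, 9.1),
    ci = c(270, 265, 280),
    leaf_temp = c(25, 25, 25),
    co2_ref = c(400, 400, 400),
    pressure = c(NA, NA, NA),
    stringsAsFactors = FALSE)
}

write_log_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force (vcmax, jmax) grid with r_day profiled out analytically;
# refine > 0 zooms the grid around the incumbent that many times
aci_grid_rss <- function(curve, n_grid = 50, refine = 0,
                         constants = kinetic_constants()) {
  eval_grid <- function(vs, js) {
    best <- list(rss = Inf, v = NA, j = NA)
    for (v in vs) for (j in js) {
      m <- pmin(rubisco_limited_rate(curve$ci, v, constants),
                rubp_limited_rate(curve$ci, j, constants))
      r <- max(mean(m - curve$a_net), 0)  # profiled r_day, bounded >= 0
      rss <- sum((curve$a_net - (m - r))^2)
      if (rss < best$rss) best <- list(rss = rss, v = v, j = j)
    }
    best
  }
  vs <- seq(5, 60, length.out = n_grid)
  js <- seq(5, 120, length.out = n_grid)
  best <- eval_grid(vs, js)
  span_v <- diff(range(vs)) / (n_grid - 1)
  span_j <- diff(range(js)) / (n_grid - 1)
  for (i in seq_len(refine)) {
    vs <- seq(best$v - 2 * span_v, best$v + 2 * span_v, length.out = 21)
    js <- seq(best$j - 2 * span_j, best$j + 2 * span_j, length.out = 21)
    best <- eval_grid(pmax(vs, 0.1), pmax(js, 0.1))
    span_v <- span_v * 4 / 20
    span_j <- span_j * 4 / 20
  }
  best$rss
}
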