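#' Daily midday PPFD means from a fixed-sensor record
#'
#' Averages timestamped sensor readings per day over the midday window
#' (inclusive start, exclusive end). Days without in-window readings are
#' omitted and counted.
#'
#' @param records Data frame with columns `timestamp` (POSIXct) and `ppfd`.
#' @param window Numeric length-2 vector of fractional hours, default
#'   `c(10, 14)` (10:00 inclusive to 14:00 exclusive).
#' @return Data frame with `day_of_year`, `mean_ppfd`, `n_obs`; attribute
#'   `n_days_dropped` counts calendar days present in the input that had no
#'   in-window readings.
#' @export
daily_means <- function(records, window = c(10, 14)) {
  stopifnot(all(c("timestamp", "ppfd") %in% names(records)),
            length(window) == 2, window[1] < window[2])
  hour <- as.numeric(strftime(records$timestamp, "%H", tz = "UTC")) +
    as.numeric(strftime(records$timestamp, "%M", tz = "UTC")) / 60
  doy <- as.integer(strftime(records$timestamp, "%j", tz = "UTC"))
  keep <- hour >= window[1] & hour < window[2] & is.finite(records$ppfd)
  all_days <- unique(doy)
  if (!any(keep)) {
    out <- data.frame(day_of_year = integer(0), mean_ppfd = numeric(0),
                      n_obs = integer(0))
    attr(out, "n_days_dropped") <- length(all_days)
    return(out)
  }
  agg <- stats::aggregate(list(mean_ppfd = records$ppfd[keep]),
                          by = list(day_of_year = doy[keep]), FUN = mean)
  cnt <- stats::aggregate(list(n_obs = records$ppfd[keep]),
                          by = list(day_of_year = doy[keep]), FUN = length)
  out <- merge(agg, cnt, by = "day_of_year")
  out <- out[order(out$day_of_year), ]
  rownames(out) <- NULL
  attr(out, "n_days_dropped") <- length(setdiff(all_days, out$day_of_year))
  out
}

#' Penalized-spline smooth of a seasonal PPFD series, with derivative
#'
#' Fits `mean_ppfd ~ s(day_of_year)` with a penalized cubic regression
#' spline ([mgcv::gam()]); the smoothing parameter is chosen by REML by
#' default (GCV available), since REML is markedly more stable against
#' undersmoothing on noisy seasonal series and that stability carries
#' directly into the derivative band the closure scan relies on. The first
#' derivative of the smooth and its
#' pointwise 95 % confidence band are obtained from the basis: the linear
#' predictor matrix is evaluated on a fine grid, differenced at step `h`,
#' and the band computed from the coefficient covariance.
#'
#' @param series Data frame with `day_of_year` and `mean_ppfd` (e.g. from
#'   [daily_means()] or [simulate_season()]).
#' @param k Spline basis dimension (default 25, capped at the number of
#'   days minus 2): generous enough to track a canopy-closure decline over
#'   a couple of weeks, with REML shrinking unused flexibility.
#' @param method Smoothing-parameter criterion: `"REML"` (default) or
#'   `"GCV.Cp"`.
#' @param min_days Fewer distinct days than this is refused.
#' @param h Central-difference step (days) for the derivative.
#' @return Object of class `canopy_smooth`: `day` (integer grid over the
#'   observed range), `fitted`, `se_fit`, `deriv`, `deriv_se`, `deriv_lo`,
#'   `deriv_hi` (95 % band) and the underlying `gam` object.
#' @export
fit_canopy_smooth <- function(series, k = 25, method = "REML",
                              min_days = 15, h = 1e-3) {
  stopifnot(all(c("day_of_year", "mean_ppfd") %in% names(series)))
  series <- series[is.finite(series$mean_ppfd), ]
  n_days <- length(unique(series$day_of_year))
  if (n_days < min_days) {
    stop("refusing to smooth: ", n_days, " distinct days (need >= ",
         min_days, ")")
  }
  k <- min(k, n_days - 2)
  g <- mgcv::gam(mean_ppfd ~ s(day_of_year, bs = "cr", k = k),
                 data = series, method = method)
  day <- seq(min(series$day_of_year), max(series$day_of_year), by = 1L)
  pf <- mgcv::predict.gam(g, data.frame(day_of_year = day), se.fit = TRUE)
  x_up <- mgcv::predict.gam(g, data.frame(day_of_year = day + h),
                            type = "lpmatrix")
  x_dn <- mgcv::predict.gam(g, data.frame(day_of_year = day - h),
                            type = "lpmatrix")
  xd <- (x_up - x_dn) / (2 * h)
  deriv <- as.numeric(xd %*% stats::coef(g))
  deriv_se <- sqrt(rowSums((xd %*% g$Vp) * xd))
  z <- stats::qnorm(0.975)
  structure(list(day = day, fitted = as.numeric(pf$fit),
                 se_fit = as.numeric(pf$se.fit),
                 deriv = deriv, deriv_se = deriv_se,
                 deriv_lo = deriv - z * deriv_se,
                 deriv_hi = deriv + z * deriv_se,
                 gam = g), class = "canopy_smooth")
}

#' Detect the day of complete canopy closure
#'
#' A decline must exist: at least one day whose derivative 95 % band lies
#' entirely below zero (its first such day is reported as `decline_start`).
#' The scan for closure then runs forward from the steepest point of the
#' decline (the most negative smoothed derivative): canopy closure is the
#' first subsequent day at which the band contains zero, i.e. the slope is
#' no longer significantly different from zero. Anchoring the scan at the
#' steepest descent rather than the first significant day keeps transient
#' near-zero wiggles early in a long gentle decline from being mistaken for
#' the plateau. Returns `NA` with a diagnostic reason when the slope is
#' never significantly negative (no decline) or never flattens within the
#' observed range.
#'
#' @param smooth A [fit_canopy_smooth()] result.
#' @return A list of class `closure_day`: `day` (integer or `NA`),
#'   `decline_start` (integer or `NA`), `reason` (`"ok"`, `"no_decline"`,
#'   `"no_plateau"`).
#' @export
closure_day <- function(smooth) {
  stopifnot(inherits(smooth, "canopy_smooth"))
  neg <- smooth$deriv_hi < 0
  if (!any(neg)) {
    return(structure(list(day = NA_integer_, decline_start = NA_integer_,
                          reason = "no_decline"), class = "closure_day"))
  }
  start <- which(neg)[1]
  anchor <- which.min(smooth$deriv)
  after <- which(smooth$deriv_lo <= 0 & smooth$deriv_hi >= 0 &
                   seq_along(smooth$day) > anchor)
  if (length(after) == 0) {
    return(structure(list(day = NA_integer_,
                          decline_start = smooth$day[start],
                          reason = "no_plateau"), class = "closure_day"))
  }
  structure(list(day = smooth$day[after[1]],
                 decline_start = smooth$day[start], reason = "ok"),
            class = "closure_day")
}

#' @export
print.closure_day <- function(x, ...) {
  if (is.na(x$day)) {
    cat("canopy closure: not detected (", x$reason, ")\n")
  } else {
    cat(sprintf("canopy closure: day %d (decline began day %d)\n",
                x$day, x$decline_start))
  }
  invisible(x)
}

.lmm_formulas <- list(
  base = log_ppfd ~ 1,
  time = log_ppfd ~ dayc,
  time2 = log_ppfd ~ dayc + I(dayc^2),
  fencing = log_ppfd ~ dayc + I(dayc^2) + treatment,
  interaction = log_ppfd ~ dayc + I(dayc^2) + treatment + dayc:treatment)

# total parameter count (fixed effects + RE sd + variance-function
# exponents + residual sd); logLik's df attribute carries exactly this
.lmm_nparams <- function(model) {
  as.integer(attr(stats::logLik(model), "df"))
}

#' Heteroscedastic mixed model of plant-level light availability
#'
#' Models `log(mean_ppfd)` as a function of day of year (centred), its
#' square, fencing treatment and the day-by-fencing interaction, with a day
#' random intercept and residual sd proportional to `day^delta` with a
#' separate exponent per treatment ([nlme::varPower()]). All models in the
#' nested sequence (intercept-only, +day, +day^2, +fencing,
#' +day-by-fencing) are fit by maximum likelihood so that likelihood ratio
#' tests of fixed effects are valid; the term table reports each successive
#' comparison with its `(k, k+1)` parameter-count pair.
#'
#' @param data Data frame of plant-level summaries: `treatment`
#'   (`"fenced"`/`"unfenced"`), `day_of_year`, `mean_ppfd` (> 0).
#' @param log_transform Model `log(mean_ppfd)` (default) or the raw scale
#'   (used internally by [treatment_means_original_scale()]).
#' @param heteroscedastic Include the treatment-specific power-of-day
#'   variance function (default `TRUE`).
#' @return Object of class `ppfd_lmm`: `model` (the full [nlme::lme()]
#'   fit), `models` (the nested sequence), `term_table` (term, df pair,
#'   likelihood ratio, p, stars), `logLik`, `n_params`, `converged`,
#'   `day_center`, `data`.
#' @export
fit_ppfd_lmm <- function(data, log_transform = TRUE, heteroscedastic = TRUE) {
  stopifnot(all(c("treatment", "day_of_year", "mean_ppfd") %in% names(data)),
            length(unique(data$treatment)) == 2,
            length(unique(data$day_of_year)) >= 2)
  if (log_transform) stopifnot(all(data$mean_ppfd > 0))
  d <- data.frame(
    log_ppfd = if (log_transform) log(data$mean_ppfd) else data$mean_ppfd,
    dayc = data$day_of_year - mean(data$day_of_year),
    day_raw = data$day_of_year,
    treatment = factor(data$treatment, levels = c("fenced", "unfenced")),
    day_f = factor(data$day_of_year))
  wts <- if (heteroscedastic) {
    nlme::varPower(form = ~ day_raw | treatment)
  } else NULL

  fit_one <- function(form) {
    tryCatch(
      nlme::lme(form, random = ~ 1 | day_f, weights = wts, data = d,
                method = "ML",
                control = nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                                           returnObject = TRUE)),
      error = function(e) NULL)
  }
  models <- lapply(.lmm_formulas, fit_one)
  converged <- !vapply(models, is.null, logical(1))
  if (!converged[["interaction"]]) {
    stop("heteroscedastic mixed model failed to fit the full model")
  }

  steps <- data.frame(term = c("Time", "Time^2", "Fencing",
                               "Time x fencing"),
                      reduced = c("base", "time", "time2", "fencing"),
                      full = c("time", "time2", "fencing", "interaction"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(steps)), function(i) {
    mf <- models[[steps$full[i]]]
    mr <- models[[steps$reduced[i]]]
    if (is.null(mf) || is.null(mr)) {
      return(data.frame(term = steps$term[i], df = NA_character_,
                        likelihood_ratio = NA_real_, p = NA_real_,
                        signif = ""))
    }
    lt <- lr_test(mf, mr)
    data.frame(term = steps$term[i],
               df = sprintf("(%d,%d)", lt$n_params_reduced,
                            lt$n_params_full),
               likelihood_ratio = lt$statistic, p = lt$p,
               signif = .stars(lt$p))
  })
  term_table <- do.call(rbind, rows)

  full <- models[["interaction"]]
  structure(list(model = full, models = models, term_table = term_table,
                 logLik = as.numeric(stats::logLik(full)),
                 n_params = .lmm_nparams(full),
                 converged = all(converged),
                 heteroscedastic = heteroscedastic,
                 log_transform = log_transform,
                 day_center = mean(data$day_of_year),
                 day_range = range(data$day_of_year),
                 data = d), class = "ppfd_lmm")
}

.stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else
    if (p < 0.1) "+" else ""
}

#' Likelihood ratio test of nested models
#'
#' `2 * (logLik_full - logLik_reduced)` against the chi-squared upper tail
#' with df equal to the parameter-count difference. Both models must be fit
#' by maximum likelihood (not REML) when fixed effects differ. A slightly
#' negative statistic (numerical noise from imperfect optimisation) is
#' clipped to zero with a warning.
#'
#' @param full,reduced Nested model fits: [nlme::lme()] objects,
#'   [lme4] fits, or any objects with a [stats::logLik()] method (the
#'   parameter counts are taken from the `df` attribute of `logLik`, except
#'   for `lme` fits where the variance-function parameters are counted
#'   explicitly).
#' @return List with `statistic`, `df`, `p`, `n_params_full`,
#'   `n_params_reduced`.
#' @export
lr_test <- function(full, reduced) {
  np <- function(m) as.integer(attr(stats::logLik(m), "df"))
  ll_f <- as.numeric(stats::logLik(full))
  ll_r <- as.numeric(stats::logLik(reduced))
  k_f <- np(full)
  k_r <- np(reduced)
  if (k_r > k_f) stop("'reduced' has more parameters than 'full'")
  stat <- 2 * (ll_f - ll_r)
  if (stat < 0) {
    if (stat < -1e-6) {
      warning("negative LR statistic (", signif(stat, 3),
              ") clipped to 0: optimisation noise in nested fits")
    }
    stat <- 0
  }
  df <- k_f - k_r
  p <- if (df == 0) as.numeric(stat <= 0) else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p,
       n_params_full = k_f, n_params_reduced = k_r)
}

#' Treatment PPFD means on the original scale
#'
#' Re-fits the selected fixed-effect structure on untransformed `mean_ppfd`
#' (same random effect and variance structure) and reports the predicted
#' population-level treatment means with standard errors at a given day.
#' Days outside the observed range are refused rather than extrapolated.
#'
#' @param fit A [fit_ppfd_lmm()] result (its `data` slot carries the
#'   original observations).
#' @param day Day of year at which to predict.
#' @return Data frame with `treatment`, `day_of_year`, `mean_ppfd`, `se`.
#' @export
treatment_means_original_scale <- function(fit, day) {
  stopifnot(inherits(fit, "ppfd_lmm"), length(day) == 1)
  if (day < fit$day_range[1] || day > fit$day_range[2]) {
    stop("day ", day, " outside the observed range [",
         fit$day_range[1], ", ", fit$day_range[2], "]; refusing to ",
         "extrapolate")
  }
  raw <- data.frame(treatment = fit$data$treatment,
                    day_of_year = fit$data$day_raw,
                    mean_ppfd = if (fit$log_transform) exp(fit$data$log_ppfd)
                    else fit$data$log_ppfd)
  refit <- fit_ppfd_lmm(raw, log_transform = FALSE,
                        heteroscedastic = fit$heteroscedastic)
  m <- refit$model
  dayc <- day - refit$day_center
  newd <- data.frame(dayc = dayc, treatment = factor(c("fenced", "unfenced"),
                                                     levels = c("fenced",
                                                                "unfenced")))
  x <- stats::model.matrix(~ dayc + I(dayc^2) + treatment + dayc:treatment,
                           newd)
  beta <- nlme::fixef(m)
  v <- stats::vcov(m)
  est <- as.numeric(x %*% beta)
  se <- sqrt(rowSums((x %*% v) * x))
  data.frame(treatment = c("fenced", "unfenced"), day_of_year = day,
             mean_ppfd = est, se = se)
}
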