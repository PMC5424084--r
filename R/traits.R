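#' Seasonal Asat ANOVA with fencing-by-month structure
#'
#' Ordinary least squares model of light-saturated photosynthetic rate with
#' fixed factors of fencing treatment and month and their interaction.
#' A log transform is applied when the residual diagnostic triggers
#' (`transform = "auto"`): absolute skewness of the raw-scale residuals
#' above `skew_limit`, or a Breusch-Pagan heteroscedasticity statistic with
#' p below `bp_alpha`. The transform choice is recorded on the result, never
#' silent.
#'
#' @param records Data frame with columns `asat`, `treatment`
#'   (`"fenced"`/`"unfenced"`), `month`.
#' @param transform `"auto"`, `"log"` or `"none"`.
#' @param skew_limit,bp_alpha Diagnostic thresholds for `"auto"`.
#' @return Object of class `asat_anova`: `model` (the `lm` fit on cell
#'   means parameterisation `asat ~ treatment * month`), `anova` (the
#'   F table), `log_transformed`, `residual_df`, `data`.
#' @export
asat_anova <- function(records, transform = c("auto", "log", "none"),
                       skew_limit = 1, bp_alpha = 0.01) {
  transform <- match.arg(transform)
  stopifnot(all(c("asat", "treatment", "month") %in% names(records)))
  d <- data.frame(asat = records$asat,
                  treatment = factor(records$treatment,
                                     levels = c("fenced", "unfenced")),
                  month = factor(records$month))
  d <- d[is.finite(d$asat), ]
  if (nlevels(droplevels(d$month)) < 2 ||
      nlevels(droplevels(d$treatment)) < 2) {
    stop("need >= 2 months and both treatments")
  }
  use_log <- switch(transform,
                    log = TRUE,
                    none = FALSE,
                    auto = {
                      m0 <- stats::lm(asat ~ treatment * month, data = d)
                      r <- stats::residuals(m0)
                      skew <- mean((r - mean(r))^3) /
                        (mean((r - mean(r))^2)^1.5)
                      # Breusch-Pagan: n * R^2 of squared residuals on fitted
                      aux <- stats::lm(I(r^2) ~ stats::fitted(m0))
                      bp <- length(r) * summary(aux)$r.squared
                      bp_p <- stats::pchisq(bp, df = 1, lower.tail = FALSE)
                      abs(skew) > skew_limit || bp_p < bp_alpha
                    })
  if (use_log && any(d$asat <= 0)) {
    stop("log transform requested/triggered but asat has non-positive ",
         "values")
  }
  d$y <- if (use_log) log(d$asat) else d$asat
  m <- stats::lm(y ~ treatment * month, data = d)
  structure(list(model = m, anova = stats::anova(m),
                 log_transformed = use_log,
                 residual_df = stats::df.residual(m), data = d),
            class = "asat_anova")
}

#' Within-month fenced-vs-unfenced contrasts
#'
#' For each month, tests the unfenced-minus-fenced difference using the
#' pooled residual variance and residual degrees of freedom of the seasonal
#' ANOVA (t-tests on the full-model contrast, not per-month subsets).
#' Months in which a treatment is absent are flagged and reported without a
#' test. No multiplicity adjustment by default; Bonferroni optional.
#'
#' @param fit An [asat_anova()] result.
#' @param months Months to test (default: all in the data).
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return Data frame with `month`, `estimate` (unfenced minus fenced, on
#'   the model scale), `se`, `t`, `df`, `p`, `signif`, `tested`.
#' @export
monthly_contrasts <- function(fit, months = NULL,
                              adjust = c("none", "bonferroni")) {
  stopifnot(inherits(fit, "asat_anova"))
  adjust <- match.arg(adjust)
  d <- fit$data
  if (is.null(months)) months <- levels(droplevels(d$month))
  beta <- stats::coef(fit$model)
  v <- stats::vcov(fit$model)
  df <- fit$residual_df
  rows <- lapply(months, function(mo) {
    present <- table(droplevels(d$treatment[d$month == mo]))
    if (length(present) < 2 || any(present == 0)) {
      return(data.frame(month = mo, estimate = NA_real_, se = NA_real_,
                        t = NA_real_, df = df, p = NA_real_, signif = "",
                        tested = FALSE))
    }
    # contrast: (unfenced - fenced) at month mo under treatment*month coding
    newf <- data.frame(treatment = factor(c("fenced", "unfenced"),
                                          levels = levels(d$treatment)),
                       month = factor(mo, levels = levels(d$month)))
    x <- stats::model.matrix(~ treatment * month, newf)
    cvec <- x[2, ] - x[1, ]
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% v %*% cvec))
    tval <- est / se
    p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    data.frame(month = mo, estimate = est, se = se, t = tval, df = df,
               p = p, signif = "", tested = TRUE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "bonferroni") {
    out$p <- pmin(out$p * sum(out$tested), 1)
  }
  out$signif <- vapply(out$p, .stars, character(1))
  rownames(out) <- NULL
  out
}

#' Mixed-model likelihood ratio test for a fencing effect on a trait
#'
#' Compares, by likelihood ratio (chi-squared, 1 df, ML fits), the linear
#' mixed model for a trait with and without the fencing fixed effect.
#' Random intercepts for individual and/or measurement date are included as
#' requested; for curve-derived parameters, observations can be weighted by
#' estimate precision. The printed weighting convention is `1 / SE`
#' (weights enter the likelihood as inverse residual-variance multipliers);
#' an inverse-variance option (`1 / SE^2`) is provided as a non-default
#' alternative.
#'
#' @param data Data frame with `value`, `treatment` and (as needed)
#'   `plant_id`, `date_id`, `se` columns.
#' @param random_effects Character subset of `c("individual", "date")`.
#' @param weights `"none"` (default for directly measured traits),
#'   `"inverse_se"` (curve parameters; uses the `se` column) or
#'   `"inverse_var"`.
#' @param trait Label carried through to the result and reports.
#' @return Object of class `trait_comparison`: `trait` (attribute label),
#'   `means` (per-treatment weighted mean and SE via
#'   [weighted_group_mean()], plus model-based estimates), `chi_sq`, `df`,
#'   `p`, `signif`, `boundary` (singular variance component flag),
#'   `models`.
#' @export
trait_lrt <- function(data, random_effects = c("individual", "date"),
                      weights = c("none", "inverse_se", "inverse_var"),
                      trait = "trait") {
  weights <- match.arg(weights)
  stopifnot(all(c("value", "treatment") %in% names(data)))
  random_effects <- match.arg(random_effects,
                              c("individual", "date"), several.ok = TRUE)
  d <- data.frame(value = data$value,
                  treatment = factor(data$treatment,
                                     levels = c("fenced", "unfenced")))
  stopifnot(nlevels(droplevels(d$treatment)) == 2)
  # a random intercept needs replication: >1 level, fewer levels than rows
  # (one observation per individual makes the individual variance an alias
  # of the residual and is silently inestimable otherwise)
  re_terms <- character(0)
  if ("individual" %in% random_effects && "plant_id" %in% names(data)) {
    d$plant_id <- factor(data$plant_id)
    if (nlevels(d$plant_id) > 1 && nlevels(d$plant_id) < nrow(d)) {
      re_terms <- c(re_terms, "(1 | plant_id)")
    }
  }
  if ("date" %in% random_effects && "date_id" %in% names(data)) {
    d$date_id <- factor(data$date_id)
    if (nlevels(d$date_id) > 1 && nlevels(d$date_id) < nrow(d)) {
      re_terms <- c(re_terms, "(1 | date_id)")
    }
  }
  w <- switch(weights,
              none = rep(1, nrow(d)),
              inverse_se = {
                stopifnot("se" %in% names(data), all(data$se > 0))
                1 / data$se
              },
              inverse_var = {
                stopifnot("se" %in% names(data), all(data$se > 0))
                1 / data$se^2
              })
  d$w <- w

  fit_one <- function(rhs) {
    if (length(re_terms) > 0) {
      f <- stats::as.formula(paste("value ~", rhs, "+",
                                   paste(re_terms, collapse = " + ")))
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = d, weights = w, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore"))))
    } else {
      stats::lm(stats::as.formula(paste("value ~", rhs)), data = d,
                weights = w)
    }
  }
  m_full <- fit_one("treatment")
  m_red <- fit_one("1")
  lt <- lr_test(m_full, m_red)
  boundary <- if (inherits(m_full, "merMod")) {
    lme4::isSingular(m_full, tol = 1e-5)
  } else FALSE

  means <- do.call(rbind, lapply(c("unfenced", "fenced"), function(tr) {
    idx <- d$treatment == tr
    if (weights == "none") {
      wm <- list(mean = mean(d$value[idx]),
                 se = stats::sd(d$value[idx]) / sqrt(sum(idx)))
    } else {
      wm <- weighted_group_mean(d$value[idx], data$se[idx],
                                scheme = if (weights == "inverse_se")
                                  "inverse_se" else "inverse_var")
    }
    data.frame(treatment = tr, mean = wm$mean, se = wm$se, n = sum(idx))
  }))
  rownames(means) <- NULL

  structure(list(trait = trait, means = means,
                 chi_sq = lt$statistic, df = lt$df, p = lt$p,
                 signif = .stars(lt$p), boundary = boundary,
                 weighting = weights,
                 models = list(full = m_full, reduced = m_red)),
            class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(sprintf("%s: chi^2(%d) = %.2f, p = %.3g %s%s\n", x$trait, x$df,
              x$chi_sq, x$p, x$signif,
              if (x$boundary) "  [variance component on boundary]" else ""))
  print(x$means)
  invisible(x)
}

#' Precision-weighted group mean
#'
#' Weighted mean with weights `1 / SE` (the reporting convention for
#' curve-derived parameter summaries; inverse-variance `1 / SE^2` is the
#' non-default alternative). The SE of the weighted mean uses the standard
#' design-weight estimator
#' \deqn{SE^2 = \frac{\sum w_i (v_i - \bar v_w)^2}{(\sum w_i)^2} \cdot
#'       \frac{n}{n - 1}}
#' (a single value returns its own `se`).
#'
#' @param values Numeric estimates.
#' @param ses Their standard errors (> 0, same length).
#' @param scheme `"inverse_se"` (default) or `"inverse_var"`.
#' @return List with `mean`, `se`, `n`, `scheme`.
#' @export
weighted_group_mean <- function(values, ses,
                                scheme = c("inverse_se", "inverse_var")) {
  scheme <- match.arg(scheme)
  stopifnot(length(values) == length(ses), length(values) >= 1)
  if (any(!is.finite(ses)) || any(ses <= 0)) {
    stop("all standard errors must be finite and > 0")
  }
  w <- if (scheme == "inverse_se") 1 / ses else 1 / ses^2
  m <- sum(w * values) / sum(w)
  if (length(values) == 1) {
    return(list(mean = m, se = ses[1], n = 1L, scheme = scheme))
  }
  se <- sqrt(sum(w * (values - m)^2) / sum(w)^2 *
               length(values) / (length(values) - 1))
  list(mean = m, se = se, n = length(values), scheme = scheme)
}

#' Signed percent change between two group means
#'
#' `100 * (new - baseline) / baseline`. The unrounded value is returned in
#' `percent`; `percent_rounded` applies nearest-integer rounding, half away
#' from zero, the convention used for headline report strings.
#'
#' @param new_mean,baseline_mean Group means; `baseline_mean` must be
#'   non-zero.
#' @return List with `percent` (unrounded), `percent_rounded` (integer) and
#'   `direction` (`"increase"`, `"decrease"` or `"no_change"`).
#' @examples
#' percent_change(9.40, 6.26)$percent_rounded  # +50
#' percent_change(350, 674)$percent_rounded    # -48
#' @export
percent_change <- function(new_mean, baseline_mean) {
  if (baseline_mean == 0) stop("baseline mean is zero: percent change ",
                               "undefined")
  p <- 100 * (new_mean - baseline_mean) / baseline_mean
  r <- sign(p) * floor(abs(p) + 0.5)
  list(percent = p, percent_rounded = as.integer(r),
       direction = if (p > 0) "increase" else if (p < 0) "decrease" else
         "no_change")
}

#' Trait panel report for one or more species
#'
#' Assembles, per species, the standard nine-trait comparison panel (SLA,
#' leaf area, Amax, Rd, phi, LSP, LCP, Vcmax, Jmax) with treatment means
#' +/- 1 SE, the fencing likelihood-ratio chi-squared and significance
#' codes. Panels whose inputs exist for only one treatment (e.g. A/Ci
#' curves measured in one treatment only) are rendered with `NA` test
#' entries rather than dropped. The report is a pure function of its
#' inputs.
#'
#' @param comparisons A list of [trait_lrt()] results (or `NA` placeholders
#'   for unavailable panels), named by trait, per species: a named list
#'   `list(species = list(trait = comparison, ...), ...)`.
#' @return Data frame with `species`, `trait`, `unfenced_mean`,
#'   `unfenced_se`, `fenced_mean`, `fenced_se`, `chi_sq`, `p`, `signif`,
#'   `available`.
#' @export
table2_report <- function(comparisons) {
  traits <- c("SLA", "leaf_area", "A_max", "R_d", "phi", "LSP", "LCP",
              "V_cmax", "J_max")
  rows <- list()
  for (sp in names(comparisons)) {
    panel <- comparisons[[sp]]
    for (tr in traits) {
      cmp <- panel[[tr]]
      if (is.null(cmp) || !inherits(cmp, "trait_comparison")) {
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, trait = tr, unfenced_mean = NA_real_,
          unfenced_se = NA_real_, fenced_mean = NA_real_,
          fenced_se = NA_real_, chi_sq = NA_real_, p = NA_real_,
          signif = "", available = FALSE)
        next
      }
      mu <- cmp$means
      uf <- mu[mu$treatment == "unfenced", ]
      fe <- mu[mu$treatment == "fenced", ]
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, trait = tr,
        unfenced_mean = uf$mean, unfenced_se = uf$se,
        fenced_mean = fe$mean, fenced_se = fe$se,
        chi_sq = cmp$chi_sq, p = cmp$p, signif = cmp$signif,
        available = TRUE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
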