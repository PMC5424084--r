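#' RuBisCO kinetic constants for C3 photosynthesis at 25 degrees C
#'
#' Container for the kinetic constants used by the FvCB model. Defaults are
#' the widely used 25 C values: Kc = 40.4 Pa and Ko = 24.8 kPa
#' (Michaelis constants for carboxylation and oxygenation), O = 21 kPa
#' (oxygen partial pressure) and Gamma* = 3.7 Pa (the CO2 compensation point
#' in the absence of mitochondrial respiration). Note the mixed units: `kc`
#' and `gamma_star` are in Pa, `ko` and `o` in kPa, so `o / ko` is
#' dimensionless.
#'
#' @param kc Michaelis constant for carboxylation, Pa.
#' @param ko Michaelis constant for oxygenation, kPa.
#' @param o Oxygen partial pressure, kPa.
#' @param gamma_star CO2 compensation point without mitochondrial
#'   respiration, Pa.
#' @return A named list of class `kinetic_constants`.
#' @export
kinetic_constants <- function(kc = 40.4, ko = 24.8, o = 21, gamma_star = 3.7) {
  stopifnot(kc > 0, ko > 0, o > 0, gamma_star > 0)
  structure(list(kc = kc, ko = ko, o = o, gamma_star = gamma_star),
            class = "kinetic_constants")
}

#' RuBisCO-limited (RuBP-saturated) assimilation rate
#'
#' \deqn{A_v = V_{c,max} (C_i - \Gamma^*) / (C_i + K_c (1 + O/K_o))}
#'
#' @param ci Intercellular CO2 partial pressure, Pa. Vectorised.
#' @param v_cmax Maximum carboxylation rate, umol CO2 m-2 s-1.
#' @param constants A [kinetic_constants()] object.
#' @return Gross carboxylation-limited rate, umol CO2 m-2 s-1 (zero at
#'   `ci = gamma_star`, approaching `v_cmax` as `ci` grows).
#' @export
rubisco_limited_rate <- function(ci, v_cmax, constants = kinetic_constants()) {
  stopifnot(all(ci > 0), v_cmax > 0)
  k <- constants$kc * (1 + constants$o / constants$ko)
  v_cmax * (ci - constants$gamma_star) / (ci + k)
}

#' RuBP-regeneration-limited assimilation rate
#'
#' \deqn{A_j = J_{max} (C_i - \Gamma^*) / (4 C_i + 8 \Gamma^*)}
#'
#' @inheritParams rubisco_limited_rate
#' @param j_max Maximum electron transport rate, umol e- m-2 s-1.
#' @return Gross RuBP-limited rate, umol CO2 m-2 s-1 (asymptote `j_max / 4`).
#' @export
rubp_limited_rate <- function(ci, j_max, constants = kinetic_constants()) {
  stopifnot(all(ci > 0), j_max > 0)
  j_max * (ci - constants$gamma_star) /
    (4 * ci + 8 * constants$gamma_star)
}

#' FvCB net assimilation
#'
#' Net assimilation as the strict pointwise minimum of the RuBisCO-limited and
#' RuBP-limited rates minus daytime respiration:
#' \eqn{A_{net} = \min(A_v, A_j) - R_{day}}. No smoothing of the transition
#' and no triose-phosphate limb.
#'
#' @inheritParams rubisco_limited_rate
#' @param v_cmax,j_max,r_day FvCB parameters (umol m-2 s-1; `r_day >= 0`).
#' @return Numeric vector of net assimilation with attribute `limitation`, a
#'   character vector (`"rubisco"` or `"rubp"`) flagging the binding limb at
#'   each `ci`.
#' @export
fvcb_net <- function(ci, v_cmax, j_max, r_day,
                     constants = kinetic_constants()) {
  stopifnot(r_day >= 0)
  av <- rubisco_limited_rate(ci, v_cmax, constants)
  aj <- rubp_limited_rate(ci, j_max, constants)
  out <- pmin(av, aj) - r_day
  attr(out, "limitation") <- ifelse(av <= aj, "rubisco", "rubp")
  out
}

#' Ci at the rubisco/RuBP limitation transition
#'
#' Solves \eqn{A_v(C_i) = A_j(C_i)} for \eqn{C_i > \Gamma^*}. With
#' \eqn{K = K_c (1 + O/K_o)} the crossover is linear in `ci`:
#' \eqn{C_i^* = (J_{max} K - 8 V_{c,max} \Gamma^*) / (4 V_{c,max} - J_{max})}.
#' The crossover is scale-free: multiplying both `v_cmax` and `j_max` by a
#' constant leaves it unchanged.
#'
#' @inheritParams fvcb_net
#' @param ci_max Upper end of the physiologically searched range, Pa.
#' @return A list with `ci` (the transition, or `NA`) and `regime`:
#'   `"crossover"`, or the everywhere-limiting limb (`"rubisco"` / `"rubp"`)
#'   when no crossover lies in `(gamma_star, ci_max)`, or `"degenerate"` when
#'   the two limbs coincide in slope.
#' @export
transition_ci <- function(v_cmax, j_max, constants = kinetic_constants(),
                          ci_max = 200) {
  stopifnot(v_cmax > 0, j_max > 0)
  k <- constants$kc * (1 + constants$o / constants$ko)
  denom <- 4 * v_cmax - j_max
  if (abs(denom) < 1e-12 * (4 * v_cmax + j_max)) {
    return(list(ci = NA_real_, regime = "degenerate"))
  }
  ci_star <- (j_max * k - 8 * v_cmax * constants$gamma_star) / denom
  if (is.finite(ci_star) && ci_star > constants$gamma_star &&
      ci_star < ci_max) {
    return(list(ci = ci_star, regime = "crossover"))
  }
  probe <- (constants$gamma_star + ci_max) / 2
  av <- rubisco_limited_rate(probe, v_cmax, constants)
  aj <- rubp_limited_rate(probe, j_max, constants)
  list(ci = NA_real_, regime = if (av <= aj) "rubisco" else "rubp")
}

#' Fit the FvCB model to an A/Ci curve
#'
#' Simultaneous estimation: `v_cmax`, `j_max` and `r_day` are estimated
#' jointly by minimising the squared error of [fvcb_net()] over all points of
#' the curve at once (no manual assignment of points to limbs). Initial
#' values come from a linear fit to the low-Ci points (carboxylation-limited
#' slope, a `v_cmax` proxy) and the high-Ci plateau (a `j_max / 4` proxy),
#' with a small multi-start over `r_day`. Repeated stability-check steps
#' (e.g. the triplicate 400 umol mol-1 level of the standard sequence) are
#' retained as data. If the fitted model places every point in one limb, the
#' parameter of the other limb is unidentified and is flagged (`NA` SE).
#'
#' @param curve Data frame with numeric columns `ci` (Pa) and `a_net`
#'   (umol CO2 m-2 s-1).
#' @param constants A [kinetic_constants()] object.
#' @param min_points Minimum number of points (default 8; fewer is refused).
#' @param fix_r_day Optional non-negative value at which to fix `r_day`
#'   (e.g. an independently estimated dark respiration); default `NULL`
#'   estimates it freely.
#' @return An object of class `fvcb_fit`: list with `estimate`
#'   (`v_cmax`, `j_max`, `r_day`), `se`, `ci_transition`, `limitation`
#'   (per-point labels from the fitted model), `rss`, `n_points`,
#'   `converged`, `se_available`, `identified` (named logical per limb).
#' @export
fit_aci <- function(curve, constants = kinetic_constants(), min_points = 8,
                    fix_r_day = NULL) {
  stopifnot(is.data.frame(curve), all(c("ci", "a_net") %in% names(curve)))
  d <- curve[is.finite(curve$ci) & is.finite(curve$a_net) & curve$ci > 0,
             c("ci", "a_net")]
  if (nrow(d) < min_points) {
    stop("refusing to fit: ", nrow(d), " usable points (need >= ",
         min_points, ")")
  }
  gs <- constants$gamma_star
  k <- constants$kc * (1 + constants$o / constants$ko)

  r0 <- if (is.null(fix_r_day)) {
    max(-min(d$a_net), 0.1)
  } else fix_r_day
  # low-Ci points: Av ~ a_net + r0 => v0; high-Ci plateau => j0
  dlo <- d[order(d$ci), ][seq_len(max(3, floor(nrow(d) / 3))), ]
  v0 <- stats::median((dlo$a_net + r0) * (dlo$ci + k) /
                        pmax(dlo$ci - gs, 0.5))
  v0 <- min(max(v0, 2), 300)
  j0 <- min(max(4 * (max(d$a_net) + r0) * 1.05, 2), 800)

  # profiled grid starts: r_day enters the least-squares problem linearly
  # given the limb minimum, so it can be profiled out exactly; the strict
  # min() kink makes the RSS surface multimodal in which points each limb
  # claims, so LM is launched from the best few well-separated grid cells
  grid_starts <- {
    vs <- exp(seq(log(2), log(200), length.out = 40))
    js <- exp(seq(log(2), log(400), length.out = 40))
    cells <- expand.grid(v = vs, j = js)
    cells$r <- NA_real_
    cells$rss <- NA_real_
    for (i in seq_len(nrow(cells))) {
      m <- pmin(rubisco_limited_rate(d$ci, cells$v[i], constants),
                rubp_limited_rate(d$ci, cells$j[i], constants))
      r <- if (is.null(fix_r_day)) max(mean(m - d$a_net), 0) else fix_r_day
      cells$r[i] <- r
      cells$rss[i] <- sum((d$a_net - (m - r))^2)
    }
    cells <- cells[order(cells$rss), ]
    picked <- cells[1, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      if (nrow(picked) >= 3) break
      distinct <- all(abs(log(cells$v[i] / picked$v)) > 0.3 |
                        abs(log(cells$j[i] / picked$j)) > 0.3)
      if (distinct) picked <- rbind(picked, cells[i, ])
    }
    lapply(seq_len(nrow(picked)), function(i)
      c(v = picked$v[i], j = picked$j[i], r = max(picked$r[i], 1e-3)))
  }
  starts <- c(grid_starts,
              list(c(v = v0, j = j0, r = r0),
                   c(v = v0 * 1.5, j = j0 * 0.8, r = 0.2),
                   c(v = v0 * 0.6, j = j0 * 1.3, r = 1)))
  best <- NULL
  for (s in starts) {
    f <- tryCatch({
      if (is.null(fix_r_day)) {
        minpack.lm::nlsLM(
          a_net ~ pmin(rubisco_limited_rate(ci, v_cmax, constants),
                       rubp_limited_rate(ci, j_max, constants)) - r_day,
          data = d,
          start = list(v_cmax = s[["v"]], j_max = s[["j"]], r_day = s[["r"]]),
          lower = c(v_cmax = 0.1, j_max = 0.1, r_day = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                               ptol = 1e-12))
      } else {
        minpack.lm::nlsLM(
          a_net ~ pmin(rubisco_limited_rate(ci, v_cmax, constants),
                       rubp_limited_rate(ci, j_max, constants)) - fix_r_day,
          data = d,
          start = list(v_cmax = s[["v"]], j_max = s[["j"]]),
          lower = c(v_cmax = 0.1, j_max = 0.1),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                               ptol = 1e-12))
      }
    }, error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }

  if (is.null(best)) {
    # joint fit impossible (typically all points in one limb, so the other
    # limb's jacobian column vanishes): fit each limb alone and keep the
    # better one, with the absent limb's parameter flagged, not invented
    limb <- .fit_aci_single_limb(d, constants, r0, fix_r_day)
    if (!is.null(limb)) return(limb)
    return(structure(list(
      estimate = c(v_cmax = NA_real_, j_max = NA_real_, r_day = NA_real_),
      se = c(v_cmax = NA_real_, j_max = NA_real_, r_day = NA_real_),
      ci_transition = NA_real_, transition_regime = NA_character_,
      limitation = rep(NA_character_, nrow(d)),
      rss = NA_real_, n_points = nrow(d), converged = FALSE,
      se_available = FALSE,
      identified = c(rubisco = FALSE, rubp = FALSE)),
      class = "fvcb_fit"))
  }

  # the (v_cmax, r_day) profile is a flat ridge when few points sit on the
  # rubisco limb; polish with a derivative-free pass and restart LM from
  # any improvement it finds
  if (is.null(fix_r_day)) {
    rss_fn <- function(p) {
      if (p[1] <= 0 || p[2] <= 0 || p[3] < 0) return(1e10)
      m <- pmin(rubisco_limited_rate(d$ci, p[1], constants),
                rubp_limited_rate(d$ci, p[2], constants))
      sum((d$a_net - (m - p[3]))^2)
    }
    for (round in 1:3) {
      nm <- stats::optim(unname(stats::coef(best$fit)[c("v_cmax", "j_max",
                                                        "r_day")]),
                         rss_fn, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))
      if (nm$value >= best$rss - 1e-12) break
      f2 <- tryCatch(
        minpack.lm::nlsLM(
          a_net ~ pmin(rubisco_limited_rate(ci, v_cmax, constants),
                       rubp_limited_rate(ci, j_max, constants)) - r_day,
          data = d,
          start = list(v_cmax = nm$par[1], j_max = nm$par[2],
                       r_day = max(nm$par[3], 0)),
          lower = c(v_cmax = 0.1, j_max = 0.1, r_day = 0),
          control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                               ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(f2)) break
      rss2 <- sum(stats::residuals(f2)^2)
      if (rss2 >= best$rss - 1e-12) break
      best <- list(fit = f2, rss = rss2)
    }
  }

  cf <- stats::coef(best$fit)
  est <- c(v_cmax = unname(cf[["v_cmax"]]), j_max = unname(cf[["j_max"]]),
           r_day = if (is.null(fix_r_day)) unname(cf[["r_day"]]) else
             fix_r_day)
  pred <- fvcb_net(d$ci, est[["v_cmax"]], est[["j_max"]], est[["r_day"]],
                   constants)
  lim <- attr(pred, "limitation")
  identified <- c(rubisco = any(lim == "rubisco"), rubp = any(lim == "rubp"))

  se_fit <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                     error = function(e) NULL)
  se <- c(v_cmax = NA_real_, j_max = NA_real_, r_day = NA_real_)
  if (!is.null(se_fit) && all(is.finite(se_fit))) {
    se[names(se_fit)] <- se_fit
  }
  if (!identified[["rubisco"]]) se[["v_cmax"]] <- NA_real_
  if (!identified[["rubp"]]) se[["j_max"]] <- NA_real_

  tr <- transition_ci(est[["v_cmax"]], est[["j_max"]], constants)
  structure(list(
    estimate = est, se = se,
    ci_transition = tr$ci,
    transition_regime = tr$regime,
    limitation = lim,
    rss = best$rss, n_points = nrow(d), converged = TRUE,
    se_available = !is.null(se_fit) && all(is.finite(se_fit)),
    identified = identified), class = "fvcb_fit")
}

.fit_aci_single_limb <- function(d, constants, r0, fix_r_day) {
  fit_limb <- function(limb) {
    tryCatch({
      if (limb == "rubisco") {
        if (is.null(fix_r_day)) {
          minpack.lm::nlsLM(
            a_net ~ rubisco_limited_rate(ci, v_cmax, constants) - r_day,
            data = d, start = list(v_cmax = 25, r_day = r0),
            lower = c(v_cmax = 0.1, r_day = 0))
        } else {
          minpack.lm::nlsLM(
            a_net ~ rubisco_limited_rate(ci, v_cmax, constants) - fix_r_day,
            data = d, start = list(v_cmax = 25), lower = c(v_cmax = 0.1))
        }
      } else {
        if (is.null(fix_r_day)) {
          minpack.lm::nlsLM(
            a_net ~ rubp_limited_rate(ci, j_max, constants) - r_day,
            data = d, start = list(j_max = 50, r_day = r0),
            lower = c(j_max = 0.1, r_day = 0))
        } else {
          minpack.lm::nlsLM(
            a_net ~ rubp_limited_rate(ci, j_max, constants) - fix_r_day,
            data = d, start = list(j_max = 50), lower = c(j_max = 0.1))
        }
      }
    }, error = function(e) NULL)
  }
  fits <- list(rubisco = fit_limb("rubisco"), rubp = fit_limb("rubp"))
  rss <- vapply(fits, function(f) if (is.null(f)) Inf else
    sum(stats::residuals(f)^2), numeric(1))
  if (all(!is.finite(rss))) return(NULL)
  limb <- names(which.min(rss))
  f <- fits[[limb]]
  cf <- stats::coef(f)
  est <- c(v_cmax = NA_real_, j_max = NA_real_,
           r_day = if (is.null(fix_r_day)) unname(cf[["r_day"]]) else
             fix_r_day)
  se <- c(v_cmax = NA_real_, j_max = NA_real_, r_day = NA_real_)
  se_f <- tryCatch(sqrt(diag(stats::vcov(f))), error = function(e) NULL)
  par <- if (limb == "rubisco") "v_cmax" else "j_max"
  est[[par]] <- unname(cf[[par]])
  if (!is.null(se_f) && all(is.finite(se_f))) {
    se[names(se_f)] <- se_f
  }
  structure(list(
    estimate = est, se = se,
    ci_transition = NA_real_, transition_regime = limb,
    limitation = rep(limb, nrow(d)),
    rss = min(rss), n_points = nrow(d), converged = TRUE,
    se_available = !is.null(se_f) && all(is.finite(se_f)),
    identified = c(rubisco = limb == "rubisco", rubp = limb == "rubp")),
    class = "fvcb_fit")
}

#' @export
print.fvcb_fit <- function(x, ...) {
  cat("FvCB A/Ci fit (simultaneous estimation)\n")
  if (!x$converged) {
    cat("  NOT CONVERGED\n")
    return(invisible(x))
  }
  print(data.frame(estimate = signif(x$estimate, 4), se = signif(x$se, 3)))
  cat(sprintf("  transition Ci = %.3g Pa (%s)  RSS = %.3g (n = %d)\n",
              x$ci_transition, x$transition_regime, x$rss, x$n_points))
  if (!all(x$identified)) {
    cat("  warning: limb(s) not represented in data:",
        names(x$identified)[!x$identified], "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.fvcb_fit <- function(x, ...) {
  data.frame(v_cmax = x$estimate[["v_cmax"]], j_max = x$estimate[["j_max"]],
             r_day = x$estimate[["r_day"]],
             se_v_cmax = x$se[["v_cmax"]], se_j_max = x$se[["j_max"]],
             se_r_day = x$se[["r_day"]],
             ci_transition = x$ci_transition, rss = x$rss,
             n_points = x$n_points, converged = x$converged)
}
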