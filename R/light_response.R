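#' Non-rectangular hyperbola net assimilation
#'
#' Evaluates the four-parameter non-rectangular hyperbola (NRH) light-response
#' model
#' \deqn{A_{net} = \frac{\phi P + A_{max} - \sqrt{(\phi P + A_{max})^2 -
#'   4\theta\phi P A_{max}}}{2\theta} - R_d}
#' where \eqn{P} is PPFD. The convexity \eqn{\theta} interpolates between the
#' rectangular hyperbola (\eqn{\theta = 0}) and the Blackman limiting-response
#' (\eqn{\theta \to 1}). For \eqn{\theta} below `1e-6` the rectangular-hyperbola
#' limit \eqn{\phi P A_{max} / (\phi P + A_{max}) - R_d} is used to avoid
#' 0/0 cancellation.
#'
#' @param ppfd Photosynthetic photon flux density, umol photons m-2 s-1 (>= 0).
#'   Vectorised.
#' @param a_max Gross maximum photosynthetic rate, umol CO2 m-2 s-1 (> 0).
#' @param phi Apparent quantum yield, mol CO2 mol photons-1 (> 0).
#' @param r_d Daytime dark respiration rate, umol CO2 m-2 s-1 (>= 0).
#' @param theta Curve convexity, dimensionless, in `[0, 1)`.
#' @return Net assimilation, umol CO2 m-2 s-1 (negative below the light
#'   compensation point; equals `-r_d` at `ppfd = 0`).
#' @examples
#' nrh_anet(200, a_max = 9.40, phi = 0.077, r_d = 0.52, theta = 0.9)
#' @export
nrh_anet <- function(ppfd, a_max, phi, r_d, theta) {
  stopifnot(all(ppfd >= 0), a_max > 0, phi > 0, r_d >= 0,
            theta >= 0, theta < 1)
  s <- phi * ppfd + a_max
  if (theta < 1e-6) {
    gross <- phi * ppfd * a_max / s
  } else {
    disc <- s^2 - 4 * theta * phi * ppfd * a_max
    if (any(disc < -1e-10)) {
      stop("negative discriminant in NRH evaluation: invalid parameters")
    }
    gross <- (s - sqrt(pmax(disc, 0))) / (2 * theta)
  }
  gross - r_d
}

#' Light compensation point of an NRH fit
#'
#' PPFD at which net assimilation crosses zero (the x-axis intercept of the
#' light-response curve). Closed form
#' \eqn{LCP = R_d (A_{max} - \theta R_d) / (\phi (A_{max} - R_d))},
#' obtained by solving the NRH gross rate equal to \eqn{R_d}.
#'
#' @param fit A [fit_light_response()] result, or a named list/vector with
#'   elements `a_max`, `phi`, `r_d`, `theta`.
#' @return LCP in umol photons m-2 s-1 (0 when `r_d = 0`).
#' @export
light_compensation_point <- function(fit) {
  p <- .lr_params(fit)
  if (p[["r_d"]] == 0) return(0)
  if (p[["r_d"]] >= p[["a_max"]]) {
    stop("light compensation point undefined: r_d >= a_max")
  }
  with(as.list(p), r_d * (a_max - theta * r_d) / (phi * (a_max - r_d)))
}

#' Light saturation point of an NRH fit
#'
#' Smallest PPFD at which the gross assimilation rate (net + `r_d`) reaches
#' `fraction` of the model asymptote `a_max`. At the conventional
#' `fraction = 0.9` the closed form is
#' \eqn{LSP = 9 A_{max} (1 - 0.9\theta) / \phi}; the general form is
#' \eqn{f A_{max}(1 - \theta f) / (\phi (1 - f))}.
#'
#' @inheritParams light_compensation_point
#' @param fraction Fraction of the asymptote defining saturation, in (0, 1).
#' @return LSP in umol photons m-2 s-1.
#' @export
light_saturation_point <- function(fit, fraction = 0.9) {
  stopifnot(fraction > 0, fraction < 1)
  p <- .lr_params(fit)
  with(as.list(p),
       fraction * a_max * (1 - theta * fraction) / (phi * (1 - fraction)))
}

.lr_params <- function(fit) {
  if (inherits(fit, "light_response_fit")) {
    p <- fit$estimate
  } else {
    p <- unlist(fit)
  }
  need <- c("a_max", "phi", "r_d", "theta")
  if (!all(need %in% names(p))) {
    stop("need named parameters: ", paste(need, collapse = ", "))
  }
  p[need]
}

#' Fit a non-rectangular hyperbola to a light-response curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()]) with
#' multi-start initialisation: `phi` from the slope of the three lowest-light
#' points, `r_d` from |A_net| at minimum light, `a_max` from the mean of the
#' top-light points plus `r_d`, and `theta` started at each of
#' `theta_starts`; the start with the lowest residual sum of squares wins.
#' `theta` is constrained to `[0, 0.999]`; a solution on that boundary is
#' flagged, not hidden. Standard errors come from the final-iteration
#' covariance; a singular covariance yields `NA` SEs with
#' `se_available = FALSE` rather than a silent number.
#'
#' @param curve A data frame with numeric columns `ppfd` and `a_net` (a
#'   [group_into_curves()] curve, a [simulate_light_curve()] output, or any
#'   equivalent table).
#' @param min_levels Minimum number of distinct PPFD levels required (default
#'   5); fewer is a refusal, not a bad fit.
#' @param theta_starts Convexity starting values for the multi-start.
#' @return An object of class `light_response_fit`: a list with `estimate`
#'   (named vector `a_max`, `phi`, `r_d`, `theta`), `se`, `lcp`, `lsp`, `rss`,
#'   `n_points`, `converged`, `se_available`, `theta_boundary`.
#' @export
fit_light_response <- function(curve, min_levels = 5,
                               theta_starts = c(0.3, 0.6, 0.9)) {
  stopifnot(is.data.frame(curve), all(c("ppfd", "a_net") %in% names(curve)))
  d <- curve[is.finite(curve$ppfd) & is.finite(curve$a_net), c("ppfd", "a_net")]
  n_levels <- length(unique(d$ppfd))
  if (n_levels < min_levels) {
    stop("refusing to fit: only ", n_levels, " distinct PPFD levels (need >= ",
         min_levels, ")")
  }
  d <- d[order(d$ppfd), ]
  degenerate <- stats::sd(d$a_net) < 1e-8

  low <- utils::head(d, 3)
  r_d0 <- max(abs(d$a_net[which.min(d$ppfd)]), 0.01)
  phi0 <- if (diff(range(low$ppfd)) > 0) {
    max(stats::coef(stats::lm(a_net ~ ppfd, data = low))[2], 1e-3)
  } else 0.05
  a_max0 <- max(mean(utils::tail(d$a_net, 3)) + r_d0, 0.5)

  lower <- c(a_max = 1e-3, phi = 1e-5, r_d = 0, theta = 0)
  upper <- c(a_max = Inf, phi = 0.5, r_d = Inf, theta = 0.999)
  best <- NULL
  if (!degenerate) for (th0 in theta_starts) {
    start <- list(a_max = a_max0, phi = min(phi0, 0.4), r_d = r_d0, theta = th0)
    f <- tryCatch(
      minpack.lm::nlsLM(
        a_net ~ nrh_anet(ppfd, a_max, phi, r_d, theta),
        data = d, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }

  if (is.null(best)) {
    return(structure(list(
      estimate = c(a_max = NA_real_, phi = NA_real_, r_d = NA_real_,
                   theta = NA_real_),
      se = c(a_max = NA_real_, phi = NA_real_, r_d = NA_real_,
             theta = NA_real_),
      lcp = NA_real_, lsp = NA_real_, rss = NA_real_,
      n_points = nrow(d), converged = FALSE, se_available = FALSE,
      theta_boundary = FALSE), class = "light_response_fit"))
  }

  est <- stats::coef(best$fit)[c("a_max", "phi", "r_d", "theta")]
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit)))[names(est)],
                 error = function(e) rep(NA_real_, 4))
  se_available <- all(is.finite(se))
  if (!se_available) se <- stats::setNames(rep(NA_real_, 4), names(est))

  out <- structure(list(
    estimate = est,
    se = se,
    lcp = if (est[["r_d"]] < est[["a_max"]]) {
      light_compensation_point(est)
    } else NA_real_,
    lsp = light_saturation_point(est),
    rss = best$rss,
    n_points = nrow(d),
    converged = TRUE,
    se_available = se_available,
    theta_boundary = est[["theta"]] <= 1e-6 || est[["theta"]] >= 0.999 - 1e-6
  ), class = "light_response_fit")
  out
}

#' @export
print.light_response_fit <- function(x, ...) {
  cat("Non-rectangular hyperbola light-response fit\n")
  if (!x$converged) {
    cat("  NOT CONVERGED (", x$n_points, "points )\n")
    return(invisible(x))
  }
  tab <- data.frame(estimate = signif(x$estimate, 4),
                    se = signif(x$se, 3))
  print(tab)
  cat(sprintf("  LCP = %.3g  LSP = %.4g umol m-2 s-1   RSS = %.3g (n = %d)\n",
              x$lcp, x$lsp, x$rss, x$n_points))
  if (x$theta_boundary) cat("  note: theta on boundary\n")
  invisible(x)
}

#' @export
as.data.frame.light_response_fit <- function(x, ...) {
  data.frame(a_max = x$estimate[["a_max"]], phi = x$estimate[["phi"]],
             r_d = x$estimate[["r_d"]], theta = x$estimate[["theta"]],
             se_a_max = x$se[["a_max"]], se_phi = x$se[["phi"]],
             se_r_d = x$se[["r_d"]], se_theta = x$se[["theta"]],
             lcp = x$lcp, lsp = x$lsp, rss = x$rss, n_points = x$n_points,
             converged = x$converged, theta_boundary = x$theta_boundary)
}
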