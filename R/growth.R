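#' Evaluate a Richards-family growth curve
#'
#' The Richards model is the asymmetric sigmoid
#' `P(t) = M / (1 + alpha * exp(-M * beta * t))^gamma`, with
#' `alpha = ((M / P0)^(1/gamma) - 1) * exp(M * beta * t0)` so that
#' `P(t0) = P0`. `M` is the upper asymptote, `beta` the intrinsic growth
#' rate and `gamma` the asymmetry about the inflection point. The logistic
#' model is the `gamma = 1` special case; the Gompertz model is its
#' `gamma -> Inf` limit, `P(t) = M * exp(-alpha_g * exp(-M * beta * t))`
#' with `alpha_g = log(M / P0) * exp(M * beta * t0)`.
#'
#' @param t Time (minutes).
#' @param M,beta,gamma Curve parameters (`M, beta, gamma > 0`).
#' @param P0 Initial value (`0 < P0 < M`), anchored at `t0`.
#' @param t0 Initial time (default 0).
#' @param family `"richards"`, `"logistic"` or `"gompertz"`.
#' @return Curve values at `t`.
#' @export
#' @examples
#' richards_curve(seq(0, 180, 2), M = 1, beta = 0.05, gamma = 2, P0 = 0.01)
richards_curve <- function(t, M, beta, gamma = 1, P0, t0 = 0,
                           family = c("richards", "logistic", "gompertz")) {
  family <- match.arg(family)
  if (M <= 0 || beta <= 0 || gamma <= 0 || P0 <= 0 || P0 >= M) {
    abort("Require M, beta, gamma > 0 and 0 < P0 < M.",
          class = "capsim_config_error")
  }
  if (family == "gompertz") {
    ag <- log(M / P0) * exp(M * beta * t0)
    return(M * exp(-ag * exp(-M * beta * t)))
  }
  if (family == "logistic") gamma <- 1
  alpha <- ((M / P0)^(1 / gamma) - 1) * exp(M * beta * t0)
  M / (1 + alpha * exp(-M * beta * t))^gamma
}

richards_alpha <- function(M, beta, gamma, P0, t0, family) {
  if (family == "gompertz") log(M / P0) * exp(M * beta * t0)
  else ((M / P0)^(1 / gamma) - 1) * exp(M * beta * t0)
}

#' Fit an S-shaped growth curve to a ROI profile
#'
#' Unweighted least-squares fit of a Richards-family sigmoid to a
#' `(time, value)` profile, using Levenberg-Marquardt with multiple starting
#' points. `t0` is fixed at the first sample time and `P0` at
#' `max(first value, 1e-3 * M)` so the anchoring constant stays finite when
#' the profile starts at exactly zero (the simulator's initial condition).
#' `M` is bounded to `[max(value)/2, 2 * max(value)]`; `beta` and `gamma`
#' are kept positive through a log transform.
#'
#' @param profile A single-ROI profile tibble with >= 6 time points and
#'   non-negative values.
#' @param family `"richards"`, `"logistic"` or `"gompertz"`.
#' @param n_starts Number of multi-start initializations (default 8).
#' @return A `growth_fit` object: parameters (`M`, `beta`, `gamma`,
#'   `alpha`, `P0`, `t0`), `r_squared`, the `family`, fitted values and
#'   convergence diagnostics. Supports [tidy()], [glance()], [augment()],
#'   `predict()` and [autoplot()].
#' @export
fit_growth_curve <- function(profile,
                             family = c("richards", "logistic", "gompertz"),
                             n_starts = 8) {
  family <- match.arg(family)
  p <- one_roi(profile)
  if (nrow(p) < 6) {
    abort("Need at least 6 time points to fit a growth curve.",
          class = "capsim_config_error")
  }
  if (any(p$value < 0)) {
    abort("Profile values must be non-negative.",
          class = "capsim_config_error")
  }
  tt <- p$time_min
  yy <- p$value
  t0 <- tt[1]
  mx <- max(yy)
  if (mx <= 0) {
    abort("Profile is identically zero; nothing to fit.",
          class = "capsim_degenerate_profile_error")
  }

  # theta = (M, log beta, log gamma); gamma dropped for logistic/gompertz
  n_par <- if (family == "richards") 3L else 2L
  resid_fn <- function(theta) {
    M <- theta[1]
    beta <- exp(theta[2])
    gamma <- if (n_par == 3L) exp(theta[3]) else 1
    P0 <- max(yy[1], 1e-3 * M)
    pred <- tryCatch(
      richards_curve(tt, M, beta, gamma, P0, t0, family),
      error = function(e) rep(1e6, length(tt)))
    pred - yy
  }

  # crude rate scale: the sigmoid should traverse its range within the
  # observed window
  rate0 <- 4 / (mx * max(diff(range(tt)), 1))
  beta_grid <- rate0 * c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  gamma_grid <- c(0.5, 1, 2, 4)
  starts <- purrr::map(seq_len(n_starts), function(k) {
    th <- c(mx, log(beta_grid[(k - 1) %% length(beta_grid) + 1]))
    if (n_par == 3L) th <- c(th, log(gamma_grid[(k - 1) %% length(gamma_grid) + 1]))
    th
  })

  lower <- c(mx / 2, rep(-Inf, n_par - 1L))
  upper <- c(2 * mx, rep(Inf, n_par - 1L))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || ss < best$ss) best <- list(fit = fit, ss = ss)
  }
  if (is.null(best)) {
    abort("Growth-curve fit failed to converge from all starting points.",
          class = "capsim_fit_error")
  }

  th <- best$fit$par
  M <- th[1]; beta <- exp(th[2])
  gamma <- if (n_par == 3L) exp(th[3]) else 1
  P0 <- max(yy[1], 1e-3 * M)
  fitted <- richards_curve(tt, M, beta, gamma, P0, t0, family)
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot > 0) 1 - best$ss / ss_tot else NA_real_

  structure(
    list(family = family, M = M, beta = beta, gamma = gamma,
         alpha = richards_alpha(M, beta, gamma, P0, t0, family),
         P0 = P0, t0 = t0, r_squared = r2,
         roi_id = p$roi_id[1], data = p, fitted = fitted,
         ss_res = best$ss, n = nrow(p),
         converged = best$fit$info %in% 1:4),
    class = "growth_fit")
}

#' Fit all growth-curve families and keep the best
#'
#' Fits the Richards, logistic and Gompertz models and returns the fit with
#' the highest R-squared.
#'
#' @inheritParams fit_growth_curve
#' @return A `growth_fit`.
#' @export
select_best_fit <- function(profile, n_starts = 8) {
  fits <- purrr::map(c("richards", "logistic", "gompertz"), function(fam) {
    tryCatch(fit_growth_curve(profile, fam, n_starts), error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    abort("No growth-curve family converged.", class = "capsim_fit_error")
  }
  fits[[which.max(purrr::map_dbl(fits, "r_squared"))]]
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s: M = %.4g, beta = %.4g, gamma = %.4g, R^2 = %.4f (n = %d)\n",
              x$family, x$M, x$beta, x$gamma, x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_min else newdata$time_min %||% newdata
  richards_curve(t, object$M, object$beta, object$gamma, object$P0,
                 object$t0, object$family)
}

#' @rdname fit_growth_curve
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @method tidy growth_fit
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("M", "beta", "gamma", "alpha", "P0"),
         estimate = c(x$M, x$beta, x$gamma, x$alpha, x$P0))
}

#' @rdname fit_growth_curve
#' @method glance growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble(family = x$family, r_squared = x$r_squared, ss_res = x$ss_res,
         n = x$n, converged = x$converged)
}

#' @rdname fit_growth_curve
#' @method augment growth_fit
#' @export
augment.growth_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$data$value - x$fitted)
}

#' Fit growth curves to every ROI in a profile table
#'
#' @param profile A profile tibble (any number of ROIs).
#' @param family Passed to [fit_growth_curve()], or `"best"` to use
#'   [select_best_fit()].
#' @return One row per ROI with the fitted parameters, R-squared and the
#'   delay / log-phase-slope metrics.
#' @export
fit_profiles <- function(profile, family = "best") {
  profile |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(p, key) {
      p$roi_id <- key$roi_id
      f <- if (identical(family, "best")) select_best_fit(p)
           else fit_growth_curve(p, family)
      slope <- tryCatch(log_phase_slope(p), error = function(e) NA_real_)
      tibble(family = f$family, M = f$M, beta = f$beta, gamma = f$gamma,
             R2 = f$r_squared, delay_min = suppressWarnings(delay_time(p)),
             slope = slope)
    }) |>
    dplyr::ungroup()
}
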