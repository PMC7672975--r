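#' Root mean square error between two series
#'
#' `sqrt(sum((predicted - observed)^2) / n)` — the objective comparing
#' normalized computational and observed profiles.
#'
#' @param predicted,observed Numeric vectors of equal positive length.
#' @return Non-negative scalar.
#' @export
#' @examples
#' rmse(c(0, 1), c(1, 1))  # sqrt(0.5)
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    abort("`predicted` and `observed` must have equal length.",
          class = "capsim_alignment_error")
  }
  if (length(predicted) == 0) {
    abort("Cannot compute RMSE of empty series.",
          class = "capsim_alignment_error")
  }
  sqrt(sum((predicted - observed)^2) / length(predicted))
}

# Normalize a bare numeric series to [0, 1].
minmax <- function(v) {
  r <- range(v)
  if (diff(r) <= 0) {
    abort("Constant series cannot be min-max normalized.",
          class = "capsim_degenerate_profile_error")
  }
  (v - r[1]) / diff(r)
}

#' Build a memoizing simulation objective for saturation parameters
#'
#' Returns a function `f(c(a, n, p))` that runs the full diffusion
#' simulation on `domain` with the candidate saturation parameters, extracts
#' the mean-concentration profile of `roi`, min-max normalizes both it and
#' the target, aligns them on shared frame times and returns their RMSE.
#' Evaluations are memoized per parameter vector, and the closure keeps a
#' call counter (`attr(f, "counts")()` returns evaluations and actual
#' simulations run).
#'
#' @param domain A `capsule_domain` with initialized diffusivity.
#' @param roi A single-row [roi_spec()].
#' @param target A single-ROI profile tibble (`time_min`, `value`).
#' @param sim A [simulation_config()]; `saturation_enabled` is forced on.
#' @param sat_template A [saturation_params()] supplying everything except
#'   `a`, `n`, `p`.
#' @return The objective function.
#' @export
saturation_objective <- function(domain, roi, target,
                                 sim = simulation_config(store_diffusivity = FALSE),
                                 sat_template = saturation_params()) {
  stopifnot(inherits(domain, "capsule_domain"))
  target <- one_roi(target)
  sim$saturation_enabled <- TRUE
  sim$store_diffusivity <- FALSE
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  n_sim <- 0L
  fn <- function(par) {
    n_eval <<- n_eval + 1L
    key <- paste(sprintf("%.17g", par), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_sim <<- n_sim + 1L
    sat <- sat_template
    sat$a <- par[1]; sat$n <- par[2]; sat$p <- par[3]
    res <- run_simulation(domain, sim, sat)
    prof <- extract_profile(res, roi)
    shared <- intersect(prof$time_min, target$time_min)
    if (length(shared) < 2) {
      abort("Simulated and target profiles share fewer than 2 frame times.",
            class = "capsim_alignment_error")
    }
    yhat <- minmax(prof$value[prof$time_min %in% shared])
    yobs <- minmax(target$value[target$time_min %in% shared])
    val <- rmse(yhat, yobs)
    cache[[key]] <- val
    val
  }
  attr(fn, "counts") <- function() c(evaluations = n_eval, simulations = n_sim)
  fn
}

#' Calibrate saturation parameters against an observed profile
#'
#' Quasi-Newton (BFGS) minimization of the normalized-profile RMSE over
#' `log(a)`, `log(n)`, `log(p)` (the log transform enforces positivity),
#' with central finite-difference gradients. After convergence the fitted
#' parameters are applied capsule-wide and the RMSE is re-evaluated for
#' every ROI in `report_rois`, mirroring the benchmarking procedure in
#' which all clusters share the parameters fitted to one selected cluster.
#'
#' @inheritParams saturation_objective
#' @param init Initial `(a, n, p)` (default `c(1, 1, 1)`).
#' @param report_rois Optional [roi_spec()] tibble of additional ROIs for
#'   the per-cluster RMSE table; `targets` must then contain a matching
#'   profile per ROI.
#' @param targets Multi-ROI profile tibble paired with `report_rois`.
#' @param maxit Maximum BFGS iterations (default 60).
#' @param reltol Relative convergence tolerance on the objective
#'   (default 1e-4).
#' @return A `calibration_result`: fitted `a`, `n`, `p`, final `rmse`,
#'   `n_points`, iteration/evaluation counts, `converged` flag and a
#'   `per_cluster` tibble. Supports [tidy()] and [glance()].
#' @export
fit_saturation <- function(domain, roi, target, init = c(1, 1, 1),
                           sim = simulation_config(store_diffusivity = FALSE),
                           sat_template = saturation_params(),
                           report_rois = NULL, targets = NULL,
                           maxit = 60, reltol = 1e-4) {
  if (any(init <= 0)) {
    abort("`init` must be positive (a, n, p).", class = "capsim_config_error")
  }
  obj <- saturation_objective(domain, roi, target, sim, sat_template)
  fn_log <- function(lp) obj(exp(lp))
  gr_log <- function(lp) {
    h <- 1e-3
    vapply(seq_along(lp), function(i) {
      e <- numeric(length(lp)); e[i] <- h
      (fn_log(lp + e) - fn_log(lp - e)) / (2 * h)
    }, numeric(1))
  }
  opt <- tryCatch(
    optim(log(init), fn_log, gr_log, method = "BFGS",
          control = list(maxit = maxit, reltol = reltol)),
    error = function(e) NULL)
  if (is.null(opt)) {
    # fall back to the best evaluated point so far: re-evaluate the start
    opt <- list(par = log(init), value = fn_log(log(init)),
                counts = c(1, 0), convergence = 99L)
  }
  par <- exp(opt$par)
  counts <- attr(obj, "counts")()

  target1 <- one_roi(target)
  per_cluster <- tibble(roi_id = roi$roi_id[1], rmse = opt$value)
  if (!is.null(report_rois) && nrow(report_rois) > 0) {
    sat <- sat_template
    sat$a <- par[1]; sat$n <- par[2]; sat$p <- par[3]
    sim2 <- sim; sim2$saturation_enabled <- TRUE
    res <- run_simulation(domain, sim2, sat)
    prof <- extract_profile(res, report_rois)
    per_cluster <- purrr::map_dfr(report_rois$roi_id, function(id) {
      tg <- targets[targets$roi_id == id, ]
      if (nrow(tg) == 0) {
        abort(sprintf("No target profile supplied for ROI '%s'.", id),
              class = "capsim_alignment_error")
      }
      pr <- prof[prof$roi_id == id, ]
      shared <- intersect(pr$time_min, tg$time_min)
      tibble(roi_id = id,
             rmse = rmse(minmax(pr$value[pr$time_min %in% shared]),
                         minmax(tg$value[tg$time_min %in% shared])))
    })
  }

  structure(
    list(a = par[1], n = par[2], p = par[3], rmse = opt$value,
         n_points = nrow(target1), iterations = opt$counts[["function"]] %||% opt$counts[1],
         evaluations = counts[["simulations"]],
         converged = identical(opt$convergence, 0L),
         per_cluster = per_cluster, init = init),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> a = %.4g, n = %.4g, p = %.4g; RMSE = %.4g (%s)\n",
              x$a, x$n, x$p, x$rmse,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  %d simulations over %d points\n", x$evaluations, x$n_points))
  invisible(x)
}

#' @rdname fit_saturation
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  tibble(term = c("a", "n", "p"), estimate = c(x$a, x$n, x$p))
}

#' @rdname fit_saturation
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble(rmse = x$rmse, n_points = x$n_points,
         evaluations = x$evaluations, converged = x$converged)
}
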