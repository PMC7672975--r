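#' Saturation-law parameters
#'
#' As antibody binds the finite pool of surface antigens, transport into the
#' cells shuts down. The model expresses this as a multiplicative exponential
#' decay of cell-node diffusivity per solver step:
#' `D <- D * exp(-(dt / dt_ref) * a * C_norm^n / (1 - C_norm)^p)`, with
#' `C_norm = C / (C_inj * saturation_fraction)` clamped to
#' `[0, 1 - clamp_eps]`. Cells saturate at a concentration far below the
#' injected one: `saturation_fraction` defaults to 0.01, i.e. cells are fully
#' saturated at 1% of `C_inj`. The exponent is scaled by `dt / dt_ref`
#' (`dt_ref` default 120 s, the acquisition cadence) so the cumulative decay
#' is invariant under timestep refinement.
#'
#' @param a,n,p Dimensionless adjustable parameters (`a >= 0`, `n > 0`,
#'   `p >= 0`); all default to 1.
#' @param saturation_fraction Fraction of `C_inj` at which cells saturate.
#' @param dt_ref Reference interval (s) for the per-step exponent scaling.
#' @param clamp_eps Clamp margin keeping `C_norm` below 1.
#' @return A `saturation_params` list.
#' @export
saturation_params <- function(a = 1, n = 1, p = 1, saturation_fraction = 0.01,
                              dt_ref = 120, clamp_eps = 1e-6) {
  if (a < 0 || n <= 0 || p < 0) {
    abort("Require a >= 0, n > 0, p >= 0.", class = "capsim_config_error")
  }
  if (saturation_fraction <= 0 || saturation_fraction > 1 || dt_ref <= 0) {
    abort("Require 0 < saturation_fraction <= 1 and dt_ref > 0.",
          class = "capsim_config_error")
  }
  structure(list(a = a, n = n, p = p,
                 saturation_fraction = saturation_fraction,
                 dt_ref = dt_ref, clamp_eps = clamp_eps),
            class = "saturation_params")
}

#' Simulation schedule
#'
#' @param total_time Simulated duration in minutes (default 180).
#' @param frame_interval Frame recording interval in minutes (default 2,
#'   matching the experimental acquisition cadence); must divide
#'   `total_time`.
#' @param dt Solver timestep in seconds, or `NULL` (auto: the largest stable
#'   step that tiles `frame_interval` exactly).
#' @param cfl_safety Safety factor in (0, 1] applied to the explicit
#'   stability bound (default 0.5).
#' @param saturation_enabled Apply the saturation law each step?
#' @param store_diffusivity Record per-frame diffusivity fields?
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(total_time = 180, frame_interval = 2, dt = NULL,
                              cfl_safety = 0.5, saturation_enabled = TRUE,
                              store_diffusivity = TRUE) {
  if (total_time <= 0 || frame_interval <= 0) {
    abort("Durations must be positive.", class = "capsim_config_error")
  }
  nfr <- total_time / frame_interval
  if (abs(nfr - round(nfr)) > 1e-9) {
    abort("`frame_interval` must divide `total_time`.",
          class = "capsim_config_error")
  }
  if (cfl_safety <= 0 || cfl_safety > 1) {
    abort("`cfl_safety` must lie in (0, 1].", class = "capsim_config_error")
  }
  structure(list(total_time = total_time, frame_interval = frame_interval,
                 dt = dt, cfl_safety = cfl_safety,
                 saturation_enabled = isTRUE(saturation_enabled),
                 store_diffusivity = isTRUE(store_diffusivity)),
            class = "simulation_config")
}

#' Stable explicit timestep for the 2D diffusion stencil
#'
#' The explicit 5-point scheme is stable for
#' `dt <= dx^2 / (4 * max(D))`; this returns that bound scaled by
#' `cfl_safety`.
#'
#' @param domain A `capsule_domain` with initialized diffusivity.
#' @param cfl_safety Safety factor in (0, 1].
#' @return Timestep in seconds.
#' @export
#' @examples
#' dom <- build_domain(grid_spec()) |> init_diffusivity()
#' stable_timestep(dom, cfl_safety = 1)  # 41.67 s at dx = 5, D = 0.15
stable_timestep <- function(domain, cfl_safety = 0.5) {
  stopifnot(inherits(domain, "capsule_domain"))
  if (is.null(domain$diffusivity)) {
    abort("Domain diffusivity is not initialized.",
          class = "capsim_config_error")
  }
  D_max <- max(domain$diffusivity)
  if (D_max <= 0) {
    abort("Maximum diffusivity is zero; domain is degenerate.",
          class = "capsim_domain_error")
  }
  cfl_safety * domain$grid$dx^2 / (4 * D_max)
}

# Face diffusivities between adjacent nodes. Harmonic mean of a zero pair is
# defined as 0, making fibers exact barriers. Branch-free: when a + b = 0 the
# numerator 2ab is also 0, so dividing by max(a + b, tiny) yields exactly 0.
face_diffusivity <- function(D, mode) {
  n <- nrow(D)
  a1 <- D[-n, ]; b1 <- D[-1, ]
  a2 <- D[, -n]; b2 <- D[, -1]
  if (mode == "harmonic") {
    list(x = 2 * a1 * b1 / pmax(a1 + b1, .Machine$double.xmin),
         y = 2 * a2 * b2 / pmax(a2 + b2, .Machine$double.xmin))
  } else {
    list(x = (a1 + b1) / 2, y = (a2 + b2) / 2)
  }
}

# Bare stencil update shared by diffuse_step() and the run_simulation() hot
# loop: no validation, exterior pinning via a precomputed index.
step_kernel <- function(C, f, coef, ext_idx, C_inj) {
  n <- nrow(C)
  dCx <- f$x * (C[-1, ] - C[-n, ])
  dCy <- f$y * (C[, -1] - C[, -n])
  flux <- matrix(0, n, n)
  flux[-n, ] <- dCx
  flux[-1, ] <- flux[-1, ] - dCx
  flux[, -n] <- flux[, -n] + dCy
  flux[, -1] <- flux[, -1] - dCy
  out <- C + coef * flux
  out[ext_idx] <- C_inj
  out
}

#' Advance the concentration field by one diffusion step
#'
#' Flux-conservative explicit update of Fick's second law with per-face
#' interface diffusivities:
#' `C' = C + (dt / dx^2) * sum_faces D_face * (C_neighbor - C)`.
#' Exterior nodes are re-pinned to `C_inj` afterwards (Dirichlet condition:
#' the medium reservoir outside the capsule is effectively infinite). Mesh
#' edges exchange no flux, which is immaterial because every edge node is
#' exterior for any capsule with `capsule_radius <= side/2 - dx`.
#'
#' @param C Concentration matrix (ug/mL), indexed like `domain$labels`.
#' @param domain A `capsule_domain` with initialized diffusivity.
#' @param dt Timestep in seconds (must satisfy the stability bound).
#' @param D Optional diffusivity matrix overriding `domain$diffusivity`
#'   (used by the saturation coupling).
#' @param C_inj Exterior Dirichlet value; defaults to the domain's transport
#'   config.
#' @return Updated concentration matrix.
#' @export
diffuse_step <- function(C, domain, dt, D = NULL, C_inj = NULL) {
  D <- D %||% domain$diffusivity
  C_inj <- C_inj %||% domain$transport$C_inj %||% 13
  mode <- domain$transport$interface_mode %||% "harmonic"
  out <- step_kernel(C, face_diffusivity(D, mode), dt / domain$grid$dx^2,
                     which(domain$labels == LABEL_EXTERIOR), C_inj)
  if (anyNA(out) || any(out < -1e-9)) {
    abort(sprintf("Numerical instability (NaN or negative concentration) at dt = %g s; reduce the timestep.", dt),
          class = "capsim_instability_error")
  }
  out
}

#' Apply the binding-site saturation law for one step
#'
#' Decays the diffusivity of cancer and fibroblast nodes according to the
#' local normalized concentration (see [saturation_params()]). Medium,
#' exterior and fiber diffusivities are untouched; diffusivity never
#' increases.
#'
#' @param D Diffusivity matrix (um^2/s).
#' @param C Concentration matrix (ug/mL).
#' @param domain A `capsule_domain`.
#' @param sat A [saturation_params()].
#' @param dt Timestep in seconds.
#' @param C_inj Injection concentration; defaults to the domain's transport
#'   config.
#' @return Updated diffusivity matrix.
#' @export
saturation_step <- function(D, C, domain, sat, dt, C_inj = NULL) {
  C_inj <- C_inj %||% domain$transport$C_inj %||% 13
  cells <- domain$labels == LABEL_CANCER | domain$labels == LABEL_FIBROBLAST
  if (!any(cells)) return(D)
  C_norm <- pmin(pmax(C[cells] / (C_inj * sat$saturation_fraction), 0),
                 1 - sat$clamp_eps)
  expo <- (dt / sat$dt_ref) * sat$a * C_norm^sat$n / (1 - C_norm)^sat$p
  D[cells] <- D[cells] * exp(-expo)
  D
}

#' Run a capsule diffusion simulation
#'
#' Integrates the antibody concentration field from a zero initial condition
#' inside the capsule with the exterior held at `C_inj`, alternating
#' diffusion and (optionally) saturation sub-steps, and records frames every
#' `frame_interval` minutes. Labels are frozen for the whole run: no cell
#' growth, movement, antibody degradation or matrix remodeling.
#'
#' @param domain A `capsule_domain` with initialized diffusivity (see
#'   [init_diffusivity()]).
#' @param sim A [simulation_config()].
#' @param sat A [saturation_params()]; used only when
#'   `sim$saturation_enabled`.
#' @return A `simulation_result`: list with `times` (minutes),
#'   `concentration` (list of matrices, one per frame), `diffusivity_frames`
#'   (if stored), `domain`, and the echoed configs.
#' @export
#' @examples
#' dom <- build_domain(grid_spec(50, 1000, 350)) |> init_diffusivity()
#' res <- run_simulation(dom, simulation_config(total_time = 10))
#' res$times
run_simulation <- function(domain, sim = simulation_config(),
                           sat = saturation_params()) {
  stopifnot(inherits(domain, "capsule_domain"))
  if (is.null(domain$diffusivity)) {
    abort("Domain diffusivity is not initialized.",
          class = "capsim_config_error")
  }
  C_inj <- domain$transport$C_inj %||% 13
  frame_s <- sim$frame_interval * 60
  bound <- stable_timestep(domain, cfl_safety = 1)
  if (is.null(sim$dt)) {
    dt <- frame_s / ceiling(frame_s / (sim$cfl_safety * bound))
  } else {
    dt <- sim$dt
    if (dt > bound + 1e-12) {
      abort(sprintf("dt = %g s exceeds the stability bound %.4g s.", dt, bound),
            class = "capsim_instability_error")
    }
    sub <- frame_s / dt
    if (abs(sub - round(sub)) > 1e-9) {
      abort("`dt` must divide the frame interval exactly.",
            class = "capsim_config_error")
    }
  }
  nsub <- round(frame_s / dt)
  nframes <- round(sim$total_time / sim$frame_interval)

  ext <- domain$labels == LABEL_EXTERIOR
  C <- matrix(0, nrow(domain$labels), ncol(domain$labels))
  C[ext] <- C_inj
  D <- domain$diffusivity

  times <- seq(0, sim$total_time, by = sim$frame_interval)
  conc <- vector("list", nframes + 1L)
  dfr <- if (sim$store_diffusivity) vector("list", nframes + 1L) else NULL
  conc[[1L]] <- C
  if (!is.null(dfr)) dfr[[1L]] <- D

  # hot loop: precompute the index sets and saturation constants once
  mode <- domain$transport$interface_mode %||% "harmonic"
  ext_idx <- which(ext)
  cell_idx <- which(domain$labels == LABEL_CANCER |
                      domain$labels == LABEL_FIBROBLAST)
  coef <- dt / domain$grid$dx^2
  saturating <- sim$saturation_enabled && length(cell_idx) > 0
  if (saturating) {
    c_sat <- C_inj * sat$saturation_fraction
    sat_scale <- (dt / sat$dt_ref) * sat$a
  }
  f <- face_diffusivity(D, mode)
  for (fr in seq_len(nframes)) {
    for (s in seq_len(nsub)) {
      C <- step_kernel(C, f, coef, ext_idx, C_inj)
      if (saturating) {
        C_norm <- pmin(pmax(C[cell_idx] / c_sat, 0), 1 - sat$clamp_eps)
        D[cell_idx] <- D[cell_idx] *
          exp(-sat_scale * C_norm^sat$n / (1 - C_norm)^sat$p)
        f <- face_diffusivity(D, mode)
      }
    }
    if (anyNA(C) || any(C < -1e-9)) {
      abort(sprintf("Numerical instability at dt = %g s; reduce the timestep.",
                    dt),
            class = "capsim_instability_error")
    }
    conc[[fr + 1L]] <- C
    if (!is.null(dfr)) dfr[[fr + 1L]] <- D
  }

  structure(list(times = times, concentration = conc,
                 diffusivity_frames = dfr, domain = domain,
                 config = list(simulation = sim, saturation = sat,
                               dt = dt, C_inj = C_inj)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d frames over %g min (dt = %.4g s), %d x %d mesh\n",
              length(x$times), max(x$times), x$config$dt,
              nrow(x$concentration[[1]]), ncol(x$concentration[[1]])))
  cat(sprintf("  saturation %s; C_inj = %g ug/mL\n",
              if (x$config$simulation$saturation_enabled) "on" else "off",
              x$config$C_inj))
  invisible(x)
}
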