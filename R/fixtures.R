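#' Generate a synthetic Richards profile with multiplicative noise
#'
#' Samples the Richards curve on a time grid and perturbs each value by
#' multiplicative Gaussian noise, `value = P(t) * (1 + e)`,
#' `e ~ N(0, noise_sigma)`, clipped at zero — emulating fluorescence signal
#' fluctuation from sample drift and cell movement. Deterministic per seed.
#'
#' @inheritParams richards_curve
#' @param times Time grid in minutes.
#' @param noise_sigma Multiplicative noise standard deviation (>= 0).
#' @param seed Integer RNG seed.
#' @param roi_id Identifier for the emitted profile.
#' @return A single-ROI profile tibble.
#' @export
make_richards_profile <- function(M = 1, beta = 0.05, gamma = 2, P0 = 0.01,
                                  times = seq(0, 180, by = 2),
                                  noise_sigma = 0, seed = 1L,
                                  t0 = times[1], family = "richards",
                                  roi_id = "synthetic") {
  if (noise_sigma < 0) {
    abort("`noise_sigma` must be >= 0.", class = "capsim_config_error")
  }
  pt <- richards_curve(times, M, beta, gamma, P0, t0, family)
  set.seed(as.integer(seed))
  vals <- pmax(pt * (1 + rnorm(length(times), 0, noise_sigma)), 0)
  tibble(roi_id = roi_id, time_min = times, value = vals,
         area = NA_real_, normalized = FALSE)
}

#' Apply multiplicative noise to a profile table
#'
#' @param profile A profile tibble.
#' @param noise_sigma Multiplicative Gaussian sigma.
#' @param seed Integer RNG seed.
#' @return The perturbed tibble (values clipped at 0).
#' @export
perturb_profile <- function(profile, noise_sigma, seed = 1L) {
  set.seed(as.integer(seed))
  profile$value <- pmax(profile$value *
                          (1 + rnorm(nrow(profile), 0, noise_sigma)), 0)
  profile
}

#' Generate a pseudo-experimental fixture with hidden ground truth
#'
#' Builds a stochastic capsule, runs the full simulation with known
#' ("true") saturation parameters, extracts ROI profiles, applies
#' multiplicative noise and writes a profiles CSV plus a YAML manifest
#' recording everything needed to regenerate the files byte-for-byte —
#' including the hidden truth, which lives only in the manifest so recovery
#' tests cannot read it from the profile data. Stands in for unpublished
#' experimental fluorescence series in calibration tests.
#'
#' The global `seed` fans out with fixed offsets: `seed` drives element
#' placement and `seed + 1` the measurement noise.
#'
#' @param dir Output directory (created if needed).
#' @param grid,placement,transport A [grid_spec()], [placement_config()] and
#'   [transport_config()].
#' @param true_sat The ground-truth [saturation_params()].
#' @param rois A [roi_spec()] tibble, or `NULL` to use one ROI per placed
#'   spheroid.
#' @param sim A [simulation_config()].
#' @param noise_sigma Multiplicative noise sigma (default 0.02).
#' @param seed Integer master seed.
#' @return Invisibly, a list with `profiles` (the noisy tibble), `domain`,
#'   `manifest` and the emitted `paths`.
#' @export
make_pseudo_experiment <- function(dir,
                                   grid = grid_spec(),
                                   placement = placement_config(),
                                   transport = transport_config(),
                                   true_sat = saturation_params(),
                                   rois = NULL,
                                   sim = simulation_config(store_diffusivity = FALSE),
                                   noise_sigma = 0.02, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dom <- build_domain(grid) |>
    place_elements(placement, seed = seed) |>
    init_diffusivity(transport)
  if (is.null(rois)) {
    if (nrow(dom$spheroids) == 0) {
      abort("No spheroids placed and no `rois` given.",
            class = "capsim_config_error")
    }
    rois <- roi_spec(paste0("spheroid_", seq_len(nrow(dom$spheroids))),
                     dom$spheroids$x, dom$spheroids$y, dom$spheroids$radius)
  }
  res <- run_simulation(dom, sim, true_sat)
  clean <- extract_profile(res, rois)
  noisy <- perturb_profile(clean, noise_sigma, seed = seed + 1L)

  profiles_path <- file.path(dir, "profiles.csv")
  rois_path <- file.path(dir, "rois.csv")
  manifest_path <- file.path(dir, "manifest.yaml")
  readr::write_csv(noisy[, c("roi_id", "time_min", "value")], profiles_path)
  readr::write_csv(
    setNames(rois, c("roi_id", "center_x_um", "center_y_um", "radius_um")),
    rois_path)
  manifest <- list(
    kind = "capsim_pseudo_experiment",
    seed = as.integer(seed),
    noise_sigma = noise_sigma,
    truth = list(a = true_sat$a, n = true_sat$n, p = true_sat$p),
    grid = unclass(grid)[c("nodes_per_side", "side_length",
                           "capsule_radius", "capsule_center")],
    placement = unclass(placement),
    transport = unclass(transport)[c("D_medium", "cell_ratio", "C_inj",
                                     "interface_mode")],
    simulation = unclass(sim)[c("total_time", "frame_interval",
                                "cfl_safety")],
    saturation = unclass(true_sat)[c("saturation_fraction", "dt_ref",
                                     "clamp_eps")],
    rois = purrr::pmap(rois, function(roi_id, x, y, radius, ...)
      list(roi_id = roi_id, x = x, y = y, radius = radius)),
    files = list(profiles = basename(profiles_path),
                 rois = basename(rois_path)))
  write_yaml_cfg(manifest, manifest_path)
  invisible(list(profiles = noisy, domain = dom, manifest = manifest,
                 paths = list(profiles = profiles_path, rois = rois_path,
                              manifest = manifest_path)))
}

#' Regenerate a pseudo-experimental fixture from its manifest
#'
#' Re-runs [make_pseudo_experiment()] with the parameters stored in a
#' manifest; with the same seed the emitted CSV files are byte-identical.
#'
#' @param manifest_path Path to a fixture `manifest.yaml`.
#' @param dir Output directory (defaults to the manifest's directory).
#' @return See [make_pseudo_experiment()].
#' @export
regenerate_fixture <- function(manifest_path, dir = dirname(manifest_path)) {
  m <- read_yaml_cfg(manifest_path)
  if (!identical(m$kind, "capsim_pseudo_experiment")) {
    abort("Not a capsim fixture manifest.", class = "capsim_format_error")
  }
  make_pseudo_experiment(
    dir = dir,
    grid = grid_spec(m$grid$nodes_per_side, m$grid$side_length,
                     m$grid$capsule_radius, unlist(m$grid$capsule_center)),
    placement = do.call(placement_config,
                        m$placement[setdiff(names(m$placement), NULL)]),
    transport = do.call(transport_config, m$transport),
    true_sat = saturation_params(m$truth$a, m$truth$n, m$truth$p,
                                 m$saturation$saturation_fraction,
                                 m$saturation$dt_ref, m$saturation$clamp_eps),
    rois = purrr::map_dfr(m$rois, function(r)
      roi_spec(r$roi_id, r$x, r$y, r$radius)),
    sim = simulation_config(m$simulation$total_time,
                            m$simulation$frame_interval,
                            cfl_safety = m$simulation$cfl_safety,
                            store_diffusivity = FALSE),
    noise_sigma = m$noise_sigma, seed = m$seed)
}

#' Render a capsule domain as a label mask
#'
#' Paints each node as an `upscale` x `upscale` pixel block carrying the
#' node's mask value (0 medium/exterior, 2 cancer, 3 fibroblast, 4 fiber) —
#' the inverse of [digitize()], used for round-trip testing of the
#' digitization pipeline.
#'
#' @param domain A `capsule_domain`.
#' @param upscale Integer pixels per node side (>= 1).
#' @return Integer mask matrix with an `um_per_pixel` attribute; write it
#'   with [write_mask()].
#' @export
render_mask <- function(domain, upscale = 1L) {
  upscale <- as.integer(upscale)
  if (upscale < 1) {
    abort("`upscale` must be a positive integer.",
          class = "capsim_config_error")
  }
  codes <- matrix(0L, nrow(domain$labels), ncol(domain$labels))
  codes[domain$labels == LABEL_CANCER] <- 2L
  codes[domain$labels == LABEL_FIBROBLAST] <- 3L
  codes[domain$labels == LABEL_FIBER] <- 4L
  m <- codes[rep(seq_len(nrow(codes)), each = upscale),
             rep(seq_len(ncol(codes)), each = upscale)]
  storage.mode(m) <- "integer"
  attr(m, "um_per_pixel") <- domain$grid$dx / upscale
  m
}
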