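#' Configure the stochastic placement of tumor-microenvironment elements
#'
#' Controls how many cancer spheroids, fibroblasts (single cells and small
#' clusters) and collagen fibers are scattered inside the capsule, and the
#' preferential localization of fibroblasts towards the outer ring of the
#' capsule. Radii follow the reference geometry of the encapsulated
#' co-culture system: 11.5 um single fibroblasts, 17.5 um fibroblast
#' clusters, 30 um straight collagen fibers restricted to the four
#' orientations 0/45/90/135 degrees.
#'
#' @param n_spheroids Number of cancer-cell spheroids (default 1).
#' @param spheroid_radius Spheroid radius in um (default 50).
#' @param n_fibro_single,fibro_single_radius Count and radius (um, default
#'   11.5) of single fibroblasts.
#' @param n_fibro_cluster,fibro_cluster_radius Count and radius (um, default
#'   17.5) of fibroblast clusters.
#' @param outer_ring_fraction Fraction of the capsule radius forming the
#'   outer ring that attracts fibroblasts (default 0.2).
#' @param outer_ring_prob Probability that a fibroblast is drawn from the
#'   outer ring rather than uniformly from the disc (default 0.7).
#' @param n_fibers Number of collagen fibers (default 0).
#' @param fiber_length Fiber length in um (default 30).
#' @param fiber_orientations Allowed fiber orientations in degrees, a
#'   non-empty subset of `c(0, 45, 90, 135)`.
#' @param max_attempts Rejection-sampling attempts per element before a
#'   placement failure is raised (default 1000).
#' @return A `placement_config` list.
#' @export
placement_config <- function(n_spheroids = 1, spheroid_radius = 50,
                             n_fibro_single = 30, fibro_single_radius = 11.5,
                             n_fibro_cluster = 8, fibro_cluster_radius = 17.5,
                             outer_ring_fraction = 0.2, outer_ring_prob = 0.7,
                             n_fibers = 0, fiber_length = 30,
                             fiber_orientations = c(0, 45, 90, 135),
                             max_attempts = 1000) {
  counts <- c(n_spheroids, n_fibro_single, n_fibro_cluster, n_fibers)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Element counts must be non-negative integers.",
          class = "capsim_config_error")
  }
  radii <- c(spheroid_radius, fibro_single_radius, fibro_cluster_radius,
             fiber_length)
  if (any(radii <= 0)) {
    abort("Element radii and fiber length must be positive.",
          class = "capsim_config_error")
  }
  if (outer_ring_fraction <= 0 || outer_ring_fraction > 1) {
    abort("`outer_ring_fraction` must lie in (0, 1].",
          class = "capsim_config_error")
  }
  if (outer_ring_prob < 0 || outer_ring_prob > 1) {
    abort("`outer_ring_prob` must lie in [0, 1].",
          class = "capsim_config_error")
  }
  fiber_orientations <- as.numeric(fiber_orientations)
  if (length(fiber_orientations) == 0 ||
      !all(fiber_orientations %in% c(0, 45, 90, 135))) {
    abort("`fiber_orientations` must be a non-empty subset of {0, 45, 90, 135}.",
          class = "capsim_config_error")
  }
  structure(
    list(n_spheroids = as.integer(n_spheroids),
         spheroid_radius = spheroid_radius,
         n_fibro_single = as.integer(n_fibro_single),
         fibro_single_radius = fibro_single_radius,
         n_fibro_cluster = as.integer(n_fibro_cluster),
         fibro_cluster_radius = fibro_cluster_radius,
         outer_ring_fraction = outer_ring_fraction,
         outer_ring_prob = outer_ring_prob,
         n_fibers = as.integer(n_fibers),
         fiber_length = fiber_length,
         fiber_orientations = fiber_orientations,
         max_attempts = as.integer(max_attempts)),
    class = "placement_config")
}

# Indices [ix, iy] of nodes whose centers fall within the disc (center, radius).
disc_nodes <- function(grid, center, radius) {
  ax <- node_axis(grid)
  ix <- which(abs(ax - center[1]) <= radius)
  iy <- which(abs(ax - center[2]) <= radius)
  if (length(ix) == 0 || length(iy) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  sub <- as.matrix(expand.grid(ix = ix, iy = iy))
  d2 <- (ax[sub[, 1]] - center[1])^2 + (ax[sub[, 2]] - center[2])^2
  sub[d2 <= radius^2, , drop = FALSE]
}

# Nodes whose centers lie within dx/2 of the segment center +/- (L/2) u,
# where u is the unit vector at `angle` degrees. At 0/90 degrees this is an
# axis-aligned run; at 45/135 a diagonal staircase.
fiber_nodes <- function(grid, center, length_um, angle_deg) {
  u <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180))
  p0 <- center - (length_um / 2) * u
  p1 <- center + (length_um / 2) * u
  ax <- node_axis(grid)
  half <- grid$dx / 2
  ix <- which(ax >= min(p0[1], p1[1]) - half & ax <= max(p0[1], p1[1]) + half)
  iy <- which(ax >= min(p0[2], p1[2]) - half & ax <= max(p0[2], p1[2]) + half)
  if (length(ix) == 0 || length(iy) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  sub <- as.matrix(expand.grid(ix = ix, iy = iy))
  # distance from node center to the segment
  px <- ax[sub[, 1]] - p0[1]
  py <- ax[sub[, 2]] - p0[2]
  v <- p1 - p0
  tt <- pmin(1, pmax(0, (px * v[1] + py * v[2]) / sum(v^2)))
  d2 <- (px - tt * v[1])^2 + (py - tt * v[2])^2
  sub[d2 <= half^2, , drop = FALSE]
}

# Sample a point uniformly (by area) in the disc of radius R about center.
runif_disc <- function(center, rmin, rmax) {
  r <- sqrt(runif(1, rmin^2, rmax^2))
  th <- runif(1, 0, 2 * pi)
  center + r * c(cos(th), sin(th))
}

#' Populate a capsule with tumor-microenvironment elements
#'
#' Places the requested numbers of cancer spheroids, fibroblast singles and
#' clusters (discs) and collagen fibers (1-node-thick segments) fully inside
#' the capsule by rejection sampling, without overlap between elements.
#' Fibroblast centers are drawn from the outer annulus
#' `[(1 - outer_ring_fraction) * R, R]` with probability `outer_ring_prob`,
#' otherwise uniformly from the capsule disc. Elements are placed
#' largest-first (spheroids, fibroblast clusters, singles, fibers) to reduce
#' rejections. The result is a deterministic function of `seed`.
#'
#' @param domain A `capsule_domain` containing only `medium`/`exterior`
#'   labels (from [build_domain()]).
#' @param cfg A [placement_config()].
#' @param seed Integer RNG seed; placement is reproducible given the seed.
#' @return The domain with element labels assigned and the spheroid registry
#'   filled in. An `elements` attribute-like tibble (`domain$elements`)
#'   records every placed element (class, center, radius/length, angle).
#' @export
#' @examples
#' dom <- build_domain(grid_spec(100, 1000, 350))
#' dom <- place_elements(dom, placement_config(n_fibro_single = 5), seed = 1)
place_elements <- function(domain, cfg = placement_config(), seed = 1L) {
  stopifnot(inherits(domain, "capsule_domain"),
            inherits(cfg, "placement_config"))
  if (any(!domain$labels %in% c(LABEL_EXTERIOR, LABEL_MEDIUM))) {
    abort("`domain` already contains placed elements; start from build_domain().",
          class = "capsim_config_error")
  }
  grid <- domain$grid
  R <- grid$capsule_radius
  cc <- grid$capsule_center
  labels <- domain$labels
  set.seed(as.integer(seed))

  elements <- list()
  place_disc <- function(class_name, label_code, radius, n, fibro_bias) {
    for (k in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(cfg$max_attempts)) {
        if (fibro_bias && runif(1) < cfg$outer_ring_prob) {
          ctr <- runif_disc(cc, (1 - cfg$outer_ring_fraction) * R, R)
        } else {
          ctr <- runif_disc(cc, 0, R)
        }
        # containment: whole disc strictly inside the capsule
        if (sqrt(sum((ctr - cc)^2)) + radius >= R) next
        sub <- disc_nodes(grid, ctr, radius)
        if (nrow(sub) == 0 || any(labels[sub] != LABEL_MEDIUM)) next
        labels[sub] <<- label_code
        elements[[length(elements) + 1L]] <<-
          tibble(class = class_name, x = ctr[1], y = ctr[2],
                 radius = radius, length = NA_real_, angle = NA_real_)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("Could not place %s #%d within %d attempts.",
                      class_name, k, cfg$max_attempts),
              class = "capsim_placement_error")
      }
    }
  }

  place_disc("spheroid", LABEL_CANCER, cfg$spheroid_radius,
             cfg$n_spheroids, fibro_bias = FALSE)
  place_disc("fibro_cluster", LABEL_FIBROBLAST, cfg$fibro_cluster_radius,
             cfg$n_fibro_cluster, fibro_bias = TRUE)
  place_disc("fibro_single", LABEL_FIBROBLAST, cfg$fibro_single_radius,
             cfg$n_fibro_single, fibro_bias = TRUE)

  for (k in seq_len(cfg$n_fibers)) {
    placed <- FALSE
    for (att in seq_len(cfg$max_attempts)) {
      ang <- sample(cfg$fiber_orientations, 1)
      ctr <- runif_disc(cc, 0, R)
      if (sqrt(sum((ctr - cc)^2)) + cfg$fiber_length / 2 >= R) next
      sub <- fiber_nodes(grid, ctr, cfg$fiber_length, ang)
      if (nrow(sub) == 0 || any(labels[sub] != LABEL_MEDIUM)) next
      labels[sub] <- LABEL_FIBER
      elements[[length(elements) + 1L]] <-
        tibble(class = "fiber", x = ctr[1], y = ctr[2], radius = NA_real_,
               length = cfg$fiber_length, angle = ang)
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("Could not place fiber #%d within %d attempts.",
                    k, cfg$max_attempts),
            class = "capsim_placement_error")
    }
  }

  el <- if (length(elements)) dplyr::bind_rows(elements) else
    tibble(class = character(), x = numeric(), y = numeric(),
           radius = numeric(), length = numeric(), angle = numeric())
  sph <- dplyr::filter(el, .data$class == "spheroid")
  out <- new_capsule_domain(grid, labels,
                            spheroids = tibble(x = sph$x, y = sph$y,
                                               radius = sph$radius))
  out$elements <- el
  out$seed <- as.integer(seed)
  out
}

#' Add an explicit element to a capsule domain
#'
#' Deterministic counterpart of [place_elements()] for scripted geometries
#' (e.g. the fiber / no-fiber paired scenarios): paints one disc or fiber at
#' a stated position. Overlap with existing elements is an error.
#'
#' @param domain A `capsule_domain`.
#' @param class One of `"spheroid"`, `"fibro_single"`, `"fibro_cluster"`,
#'   `"fiber"`.
#' @param center Numeric `c(x, y)` in um.
#' @param radius Disc radius in um (disc classes).
#' @param length,angle Fiber length (um) and orientation (degrees).
#' @return The updated domain.
#' @export
add_element <- function(domain, class, center, radius = NULL,
                        length = 30, angle = 0) {
  stopifnot(inherits(domain, "capsule_domain"))
  grid <- domain$grid
  if (class == "fiber") {
    sub <- fiber_nodes(grid, center, length, angle)
    code <- LABEL_FIBER
  } else {
    stopifnot(is.numeric(radius), radius > 0)
    sub <- disc_nodes(grid, center, radius)
    code <- switch(class, spheroid = LABEL_CANCER,
                   fibro_single = , fibro_cluster = LABEL_FIBROBLAST,
                   abort("Unknown element class.", class = "capsim_config_error"))
  }
  if (nrow(sub) == 0) {
    abort("Element covers no nodes at this mesh resolution.",
          class = "capsim_config_error")
  }
  if (any(!domain$labels[sub] %in% c(LABEL_MEDIUM, LABEL_EXTERIOR))) {
    abort("Element overlaps a previously placed element.",
          class = "capsim_placement_error")
  }
  domain$labels[sub] <- code
  if (class == "spheroid") {
    domain$spheroids <- dplyr::bind_rows(
      domain$spheroids, tibble(x = center[1], y = center[2], radius = radius))
  }
  domain
}
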