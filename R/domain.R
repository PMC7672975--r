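# Node label codes. The capsule cross-section is a square mesh whose nodes
# carry exactly one tissue label; everything outside the capsule disc is
# EXTERIOR (culture medium held at the injection concentration).
LABEL_EXTERIOR   <- 0L
LABEL_MEDIUM     <- 1L
LABEL_CANCER     <- 2L
LABEL_FIBROBLAST <- 3L
LABEL_FIBER      <- 4L

#' Node label codes used in capsule domains
#'
#' Integer codes for the per-node tissue labels of a [capsule_domain()]:
#' `exterior` (0, culture medium outside the capsule), `medium` (1, alginate
#' inside the capsule), `cancer` (2, spheroid cells), `fibroblast` (3) and
#' `fiber` (4, zero-diffusivity collagen).
#'
#' @return Named integer vector of the five label codes.
#' @export
#' @examples
#' capsule_labels()
capsule_labels <- function() {
  c(exterior = LABEL_EXTERIOR, medium = LABEL_MEDIUM, cancer = LABEL_CANCER,
    fibroblast = LABEL_FIBROBLAST, fiber = LABEL_FIBER)
}

#' Define the discretization of a capsule cross-section
#'
#' The simulation domain is a square mesh of `nodes_per_side` x
#' `nodes_per_side` equally spaced nodes spanning `side_length` micrometers,
#' containing a central circular capsule of radius `capsule_radius`. Node
#' `(i, j)` (1-based) has its center at `((i - 0.5) * dx, (j - 0.5) * dx)`
#' measured from the mesh corner, with `dx = side_length / nodes_per_side`.
#'
#' @param nodes_per_side Number of nodes along each mesh side (default 200).
#' @param side_length Physical side length of the mesh in micrometers
#'   (default 1000).
#' @param capsule_radius Radius of the capsule disc in micrometers
#'   (default 350).
#' @param capsule_center Capsule center as `c(x, y)` in micrometers; defaults
#'   to the mesh center.
#' @return A `grid_spec` object (list with the four fields above plus the
#'   node spacing `dx`).
#' @export
#' @examples
#' gs <- grid_spec()
#' gs$dx  # 5 micrometers per node
grid_spec <- function(nodes_per_side = 200, side_length = 1000,
                      capsule_radius = 350, capsule_center = NULL) {
  if (!is.numeric(nodes_per_side) || length(nodes_per_side) != 1 ||
      nodes_per_side < 2 || nodes_per_side != round(nodes_per_side)) {
    abort("`nodes_per_side` must be a single integer >= 2.",
          class = "capsim_config_error")
  }
  if (!is.numeric(side_length) || side_length <= 0) {
    abort("`side_length` must be a positive length (micrometers).",
          class = "capsim_config_error")
  }
  if (!is.numeric(capsule_radius) || capsule_radius < 0 ||
      capsule_radius > side_length / 2) {
    abort("`capsule_radius` must lie in [0, side_length / 2].",
          class = "capsim_config_error")
  }
  capsule_center <- capsule_center %||% c(side_length / 2, side_length / 2)
  stopifnot(is.numeric(capsule_center), length(capsule_center) == 2)
  structure(
    list(nodes_per_side = as.integer(nodes_per_side),
         side_length = as.numeric(side_length),
         capsule_radius = as.numeric(capsule_radius),
         capsule_center = as.numeric(capsule_center),
         dx = side_length / nodes_per_side),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d nodes, %.6g um side (dx = %.6g um), capsule R = %.6g um\n",
              x$nodes_per_side, x$nodes_per_side, x$side_length, x$dx,
              x$capsule_radius))
  invisible(x)
}

# Node center coordinates along one axis (um from mesh corner).
node_axis <- function(grid) (seq_len(grid$nodes_per_side) - 0.5) * grid$dx

# Matrix of node-center distances to the capsule center. Matrix is indexed
# [ix, iy]: first index runs along x.
node_radius <- function(grid) {
  ax <- node_axis(grid)
  sqrt(outer((ax - grid$capsule_center[1])^2,
             (ax - grid$capsule_center[2])^2, "+"))
}

#' Build an empty capsule domain
#'
#' Discretizes the capsule cross-section: nodes whose centers fall within the
#' capsule disc are labeled `medium`, all others `exterior`. No tumor
#' microenvironment elements are placed and no diffusivity is assigned yet
#' (see [place_elements()] and [init_diffusivity()]).
#'
#' @param grid A [grid_spec()].
#' @return A `capsule_domain`: list with fields `grid`, `labels` (integer
#'   matrix indexed `[ix, iy]`, see [capsule_labels()]), `diffusivity`
#'   (matrix in um^2/s, `NULL` until initialized) and `spheroids` (tibble
#'   with columns `x`, `y`, `radius` in um).
#' @export
#' @examples
#' dom <- build_domain(grid_spec())
#' table(dom$labels)
build_domain <- function(grid) {
  if (!inherits(grid, "grid_spec")) grid <- do.call(grid_spec, grid)
  r <- node_radius(grid)
  labels <- matrix(LABEL_EXTERIOR, grid$nodes_per_side, grid$nodes_per_side)
  labels[r <= grid$capsule_radius] <- LABEL_MEDIUM
  new_capsule_domain(grid, labels)
}

new_capsule_domain <- function(grid, labels, diffusivity = NULL,
                               spheroids = NULL) {
  spheroids <- spheroids %||%
    tibble(x = numeric(), y = numeric(), radius = numeric())
  structure(list(grid = grid, labels = labels, diffusivity = diffusivity,
                 spheroids = spheroids),
            class = "capsule_domain")
}

#' @export
print.capsule_domain <- function(x, ...) {
  lab <- capsule_labels()
  counts <- vapply(lab, function(code) sum(x$labels == code), integer(1))
  cat(sprintf("<capsule_domain> %d x %d nodes (dx = %.4g um), capsule R = %.4g um\n",
              x$grid$nodes_per_side, x$grid$nodes_per_side, x$grid$dx,
              x$grid$capsule_radius))
  cat("  nodes:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  spheroids: %d; diffusivity %s\n", nrow(x$spheroids),
              if (is.null(x$diffusivity)) "uninitialized" else "initialized"))
  invisible(x)
}

#' Tidy a capsule domain into one row per node
#'
#' @param x A `capsule_domain`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y` (node centers, um), `label`
#'   (factor) and, when initialized, `diffusivity` (um^2/s).
#' @method as_tibble capsule_domain
#' @export
as_tibble.capsule_domain <- function(x, ...) {
  ax <- node_axis(x$grid)
  lab <- capsule_labels()
  n <- x$grid$nodes_per_side
  lbl <- factor(names(lab)[match(as.vector(x$labels), lab)],
                levels = names(lab))
  out <- tibble(x = rep(ax, times = n), y = rep(ax, each = n), label = lbl)
  if (!is.null(x$diffusivity)) out$diffusivity <- as.vector(x$diffusivity)
  out
}

#' Distance from a point to the capsule periphery
#'
#' Radial distance from `point` (inside the capsule) to the capsule boundary:
#' `capsule_radius - |point - capsule_center|`. This is the "distance to
#' capsule periphery" used to rank cell clusters by depth.
#'
#' @param domain A `capsule_domain` (or a `grid_spec`).
#' @param point Numeric `c(x, y)` in micrometers.
#' @return Distance in micrometers (>= 0).
#' @export
#' @examples
#' dom <- build_domain(grid_spec())
#' distance_to_periphery(dom, c(800, 500))  # 50 um
distance_to_periphery <- function(domain, point) {
  grid <- if (inherits(domain, "grid_spec")) domain else domain$grid
  stopifnot(is.numeric(point), length(point) == 2)
  d <- sqrt(sum((point - grid$capsule_center)^2))
  if (d > grid$capsule_radius) {
    abort("`point` lies outside the capsule disc.",
          class = "capsim_domain_error")
  }
  grid$capsule_radius - d
}
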