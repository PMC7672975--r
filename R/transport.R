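#' Transport parameters of the capsule system
#'
#' Antibody diffusivity in the culture medium and alginate (`D_medium`),
#' the factor by which cells slow diffusion (`cell_ratio`, so initial
#' `D_cell = D_medium / cell_ratio`), the injected antibody concentration
#' held fixed outside the capsule (`C_inj`), and the interface-averaging
#' rule used by the flux-conservative stencil.
#'
#' Defaults reproduce the reference system: `D_medium` 0.15 um^2/s (hence
#' `D_cell` 0.0015 um^2/s), `C_inj` 13 ug/mL.
#'
#' @param D_medium Diffusivity of the medium/alginate in um^2/s.
#' @param cell_ratio Divisor giving the initial cell diffusivity.
#' @param C_inj Injection concentration in ug/mL (Dirichlet exterior value).
#' @param interface_mode `"harmonic"` (default; zero-diffusivity fibers are
#'   exact barriers) or `"arithmetic"` face averaging.
#' @return A `transport_config` list.
#' @export
transport_config <- function(D_medium = 0.15, cell_ratio = 100, C_inj = 13,
                             interface_mode = c("harmonic", "arithmetic")) {
  if (D_medium <= 0 || cell_ratio <= 0 || C_inj <= 0) {
    abort("`D_medium`, `cell_ratio` and `C_inj` must all be positive.",
          class = "capsim_config_error")
  }
  interface_mode <- match.arg(interface_mode)
  structure(list(D_medium = D_medium, cell_ratio = cell_ratio, C_inj = C_inj,
                 interface_mode = interface_mode),
            class = "transport_config")
}

#' Initialize the diffusivity field of a capsule domain
#'
#' Assigns per-node diffusivities from the labels: `medium` and `exterior`
#' nodes get `D_medium`; fibroblast nodes get `D_cell = D_medium /
#' cell_ratio`; collagen fibers get exactly 0 (total barrier). Cancer nodes
#' belonging to a registered spheroid get a radially graded diffusivity
#' `D_cell * d / r_sph`, where `d` is the node distance to the spheroid
#' center — the spheroid core is effectively impermeable while its outer
#' layer diffuses like a single cell. Cancer nodes outside any registered
#' spheroid get the uniform `D_cell`.
#'
#' @param domain A labeled `capsule_domain`.
#' @param cfg A [transport_config()].
#' @param grade_clusters If `TRUE`, apply the same radial grading to
#'   fibroblast clusters (default `FALSE`: clusters keep uniform `D_cell`).
#' @return The domain with its `diffusivity` matrix filled in.
#' @export
#' @examples
#' dom <- build_domain(grid_spec()) |> init_diffusivity(transport_config())
#' range(dom$diffusivity)
init_diffusivity <- function(domain, cfg = transport_config(),
                             grade_clusters = FALSE) {
  stopifnot(inherits(domain, "capsule_domain"),
            inherits(cfg, "transport_config"))
  grid <- domain$grid
  D_cell <- cfg$D_medium / cfg$cell_ratio
  D <- matrix(cfg$D_medium, grid$nodes_per_side, grid$nodes_per_side)
  D[domain$labels == LABEL_FIBROBLAST] <- D_cell
  D[domain$labels == LABEL_CANCER] <- D_cell
  D[domain$labels == LABEL_FIBER] <- 0
  grade_one <- function(D, ctr, radius) {
    sub <- disc_nodes(grid, ctr, radius)
    if (nrow(sub) == 0) return(D)
    ax <- node_axis(grid)
    d <- sqrt((ax[sub[, 1]] - ctr[1])^2 + (ax[sub[, 2]] - ctr[2])^2)
    grade <- D_cell * d / radius
    keep <- domain$labels[sub] == LABEL_CANCER |
      (grade_clusters & domain$labels[sub] == LABEL_FIBROBLAST)
    D[sub[keep, , drop = FALSE]] <- grade[keep]
    D
  }
  for (k in seq_len(nrow(domain$spheroids))) {
    D <- grade_one(D, c(domain$spheroids$x[k], domain$spheroids$y[k]),
                   domain$spheroids$radius[k])
  }
  if (grade_clusters && !is.null(domain$elements)) {
    cl <- dplyr::filter(domain$elements, .data$class == "fibro_cluster")
    for (k in seq_len(nrow(cl))) {
      D <- grade_one(D, c(cl$x[k], cl$y[k]), cl$radius[k])
    }
  }
  domain$diffusivity <- D
  domain$transport <- cfg
  domain
}
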