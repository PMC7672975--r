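# Mask pixel conventions. A label mask is an integer matrix indexed
# [px, py] (first index along x, origin at the mesh corner) with values
#   0 = background / medium, 1 = cell (binary mode),
#   2 / 3 / 4 = cancer / fibroblast / fiber (labeled mode).
# An `um_per_pixel` attribute carries the physical pixel size.
MASK_VALUES <- c(0L, 1L, 2L, 3L, 4L)

#' Read a label mask from a PNG or TIFF file
#'
#' Single-channel 8-bit images whose gray levels encode the label codes
#' directly (0-4). The physical pixel size is read from a YAML sidecar
#' (`<file>.yaml`, key `um_per_pixel`) or passed explicitly.
#'
#' @param path PNG or TIFF file.
#' @param um_per_pixel Physical pixel size in um; overrides the sidecar.
#' @return Integer mask matrix `[px, py]` with an `um_per_pixel` attribute.
#' @export
read_mask <- function(path, um_per_pixel = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    abort("Mask must be a PNG or TIFF file.", class = "capsim_format_error"))
  if (length(dim(img)) == 3) img <- img[, , 1]
  vals <- round(img * 255)
  if (!all(vals %in% MASK_VALUES)) {
    abort("Mask contains pixel values outside the label convention 0-4.",
          class = "capsim_format_error")
  }
  # image rows run along y (top-down); convert to [px, py] with y upward
  m <- t(vals[rev(seq_len(nrow(vals))), , drop = FALSE])
  storage.mode(m) <- "integer"
  if (is.null(um_per_pixel)) {
    sidecar <- paste0(path, ".yaml")
    if (file.exists(sidecar)) {
      um_per_pixel <- read_yaml_cfg(sidecar)$um_per_pixel
    }
  }
  if (is.null(um_per_pixel)) {
    abort("`um_per_pixel` not given and no sidecar found.",
          class = "capsim_format_error")
  }
  attr(m, "um_per_pixel") <- um_per_pixel
  m
}

#' Write a label mask to a PNG or TIFF file with a YAML sidecar
#'
#' @param mask Integer mask matrix `[px, py]` with an `um_per_pixel`
#'   attribute (see [render_mask()]).
#' @param path Output PNG or TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  upp <- attr(mask, "um_per_pixel")
  img <- t(mask)[rev(seq_len(ncol(mask))), , drop = FALSE] / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8),
    abort("Mask must be written as PNG or TIFF.",
          class = "capsim_format_error"))
  write_yaml_cfg(list(um_per_pixel = upp), paste0(path, ".yaml"))
  invisible(path)
}

#' Digitize a labeled capsule mask onto the simulation mesh
#'
#' Downsamples a label mask to the mesh by majority vote: each pixel is
#' assigned to the node containing its center and each node takes its most
#' frequent pixel label (ties broken towards the lower label code). Mask
#' value 1 ("cell", binary mode) maps to the fibroblast label; cancer
#' spheroids — which the imaging pipeline cannot segment from a binary
#' mask — are supplied through `spheroid_spec` and override node labels,
#' registering each disc in the spheroid registry so the radial diffusivity
#' grading applies. Nodes outside the capsule disc are exterior regardless
#' of the mask.
#'
#' @param mask Integer mask matrix from [read_mask()] or [render_mask()],
#'   or a file path.
#' @param grid A [grid_spec()].
#' @param spheroid_spec Optional tibble/data.frame with columns `x`, `y`,
#'   `radius` (um) of manually added cancer spheroids.
#' @return A `capsule_domain`.
#' @export
digitize <- function(mask, grid, spheroid_spec = NULL) {
  if (is.character(mask)) mask <- read_mask(mask)
  upp <- attr(mask, "um_per_pixel")
  if (is.null(upp)) {
    abort("Mask has no `um_per_pixel` attribute.",
          class = "capsim_format_error")
  }
  if (upp > grid$dx + 1e-9) {
    abort("Mask resolution is coarser than the mesh resolution.",
          class = "capsim_format_error")
  }
  if (!all(mask %in% MASK_VALUES)) {
    abort("Mask contains values outside the label convention 0-4.",
          class = "capsim_format_error")
  }
  n <- grid$nodes_per_side
  # node index of each pixel center along one axis
  node_of <- function(np) {
    centers <- (seq_len(np) - 0.5) * upp
    idx <- floor(centers / grid$dx) + 1L
    pmin(pmax(idx, 1L), n)
  }
  ix <- node_of(nrow(mask))
  iy <- node_of(ncol(mask))
  node_lin <- rep(ix, times = ncol(mask)) +
    (rep(iy, each = nrow(mask)) - 1L) * n
  v <- as.vector(mask)
  counts <- vapply(MASK_VALUES, function(code) {
    tabulate(node_lin[v == code], nbins = n * n)
  }, integer(n * n))
  win <- max.col(counts, ties.method = "first")  # ties -> lower label code
  node_label <- MASK_VALUES[win]
  covered <- rowSums(counts) > 0

  labels <- matrix(LABEL_MEDIUM, n, n)
  labels[node_label == 1L] <- LABEL_FIBROBLAST
  labels[node_label == 2L] <- LABEL_CANCER
  labels[node_label == 3L] <- LABEL_FIBROBLAST
  labels[node_label == 4L] <- LABEL_FIBER
  labels[!covered] <- LABEL_MEDIUM
  labels[node_radius(grid) > grid$capsule_radius] <- LABEL_EXTERIOR

  dom <- new_capsule_domain(grid, labels)
  if (!is.null(spheroid_spec) && nrow(spheroid_spec) > 0) {
    for (k in seq_len(nrow(spheroid_spec))) {
      ctr <- c(spheroid_spec$x[k], spheroid_spec$y[k])
      sub <- disc_nodes(grid, ctr, spheroid_spec$radius[k])
      keep <- dom$labels[sub] != LABEL_EXTERIOR
      dom$labels[sub[keep, , drop = FALSE]] <- LABEL_CANCER
      dom$spheroids <- dplyr::bind_rows(
        dom$spheroids,
        tibble(x = ctr[1], y = ctr[2], radius = spheroid_spec$radius[k]))
    }
  }
  if (all(dom$labels %in% c(LABEL_EXTERIOR, LABEL_MEDIUM))) {
    warn("Digitized mask contains no cells; domain is an empty capsule.")
  }
  dom
}
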