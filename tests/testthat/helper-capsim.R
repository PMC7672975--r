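# Shared builders and independent oracles for the test suite.

# Small capsule for fast engine runs: 60 x 60 nodes over 300 um, R = 100 um.
small_grid <- function(n = 60, side = 300, radius = 100) {
  grid_spec(n, side, radius)
}

small_domain <- function(...) {
  init_diffusivity(build_domain(small_grid(...)), transport_config())
}

# Brute-force count of nodes whose centers fall inside the capsule disc.
count_interior_oracle <- function(grid) {
  dx <- grid$side_length / grid$nodes_per_side
  cnt <- 0L
  for (i in seq_len(grid$nodes_per_side)) {
    for (j in seq_len(grid$nodes_per_side)) {
      x <- (i - 0.5) * dx - grid$capsule_center[1]
      y <- (j - 0.5) * dx - grid$capsule_center[2]
      if (sqrt(x^2 + y^2) <= grid$capsule_radius) cnt <- cnt + 1L
    }
  }
  cnt
}

# Hand-rolled single diffusion step: double loop over nodes, harmonic
# interface diffusivities, Dirichlet re-pinning of exterior nodes.
diffuse_step_oracle <- function(C, D, labels, dx, dt, C_inj) {
  n <- nrow(C)
  hmean <- function(a, b) if (a + b > 0) 2 * a * b / (a + b) else 0
  out <- C
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
        if (nb[1] < 1 || nb[1] > n || nb[2] < 1 || nb[2] > n) next
        acc <- acc + hmean(D[i, j], D[nb[1], nb[2]]) *
          (C[nb[1], nb[2]] - C[i, j])
      }
      out[i, j] <- C[i, j] + dt / dx^2 * acc
    }
  }
  out[labels == 0L] <- C_inj
  out
}

# Rotate a square matrix by 90 degrees about its center.
rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Paint a closed square ring of fiber nodes (total barrier) directly into
# the label matrix; i/j are node index ranges.
paint_fiber_ring <- function(domain, i_range, j_range) {
  i1 <- i_range[1]; i2 <- i_range[2]; j1 <- j_range[1]; j2 <- j_range[2]
  domain$labels[i1:i2, j1] <- 4L
  domain$labels[i1:i2, j2] <- 4L
  domain$labels[i1, j1:j2] <- 4L
  domain$labels[i2, j1:j2] <- 4L
  domain
}

# Paired scenario domains: three fibroblast clusters — peripheral (depth
# 50 um), and two internal ones at ~120 um depth (deep enough to matter,
# shallow enough that the antibody reaches them within 3 h). The "fibers"
# twin adds a closed ring around one internal cluster (total isolation) and
# a partial wall on the outboard side of the other (attenuation).
make_fiber_pair <- function() {
  grid <- grid_spec(100, 1000, 350)  # dx = 10 um
  base <- build_domain(grid)
  base <- add_element(base, "fibro_cluster", c(800, 500), radius = 17.5)
  base <- add_element(base, "fibro_cluster", c(500, 730), radius = 17.5)
  base <- add_element(base, "fibro_cluster", c(270, 500), radius = 17.5)
  fib <- base
  # closed ring around the (500, 730) cluster
  fib <- paint_fiber_ring(fib, c(44, 57), c(67, 80))
  # radial-blocking wall outboard of the (270, 500) cluster
  fib$labels[20, 44:57] <- 4L
  list(no_fiber = init_diffusivity(base, transport_config()),
       fiber = init_diffusivity(fib, transport_config()))
}
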