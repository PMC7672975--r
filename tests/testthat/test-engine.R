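lab <- capsule_labels()

test_that("stable_timestep follows the explicit CFL bound", {
  dom <- build_domain(grid_spec(200, 1000, 350)) |> init_diffusivity()
  expect_equal(stable_timestep(dom, cfl_safety = 1), 5^2 / (4 * 0.15),
               tolerance = 1e-12)
  expect_equal(stable_timestep(dom, cfl_safety = 0.5), 20.833333,
               tolerance = 1e-6)
  dom2 <- dom
  dom2$diffusivity <- dom$diffusivity * 2
  expect_equal(stable_timestep(dom2, 1), stable_timestep(dom, 1) / 2)
  dom3 <- dom
  dom3$diffusivity[] <- 0
  expect_error(stable_timestep(dom3), class = "capsim_domain_error")
})

test_that("a uniform field is a fixed point of the diffusion step", {
  dom <- small_domain()
  C <- matrix(13, 60, 60)
  expect_equal(diffuse_step(C, dom, dt = 10), C)
})

test_that("one step matches the hand-rolled stencil oracle node by node", {
  gs <- grid_spec(5, 25, 10)
  dom <- build_domain(gs)
  dom$labels[3, 3] <- lab[["fibroblast"]]
  dom <- init_diffusivity(dom, transport_config())
  set.seed(42)
  C <- matrix(runif(25, 0, 13), 5, 5)
  dt <- stable_timestep(dom, 0.5)
  got <- diffuse_step(C, dom, dt)
  want <- diffuse_step_oracle(C, dom$diffusivity, dom$labels, gs$dx, dt, 13)
  expect_equal(got, want, tolerance = 1e-14)
})

test_that("harmonic interfaces make zero-diffusivity fibers fluxless", {
  gs <- grid_spec(7, 35, 15)
  dom <- build_domain(gs)
  dom$labels[4, 2:6] <- lab[["fiber"]]  # wall through the middle
  dom <- init_diffusivity(dom, transport_config())
  C <- matrix(0, 7, 7)
  C[dom$labels == 0L] <- 13
  C[2, 4] <- 5  # hot node left of the wall
  out <- diffuse_step(C, dom, stable_timestep(dom, 0.5))
  # fiber nodes receive nothing
  expect_true(all(out[4, 2:6] == 0))
})

test_that("saturation_step follows the exponential saturation law", {
  gs <- grid_spec(5, 25, 12)
  dom <- build_domain(gs)
  dom$labels[3, 3] <- lab[["cancer"]]
  dom <- init_diffusivity(dom, transport_config())
  sat <- saturation_params(a = 1, n = 1, p = 1)
  D0 <- dom$diffusivity

  # zero concentration: no decay anywhere
  C <- matrix(0, 5, 5)
  expect_equal(saturation_step(D0, C, dom, sat, dt = 120), D0)

  # C_norm = 0.5 at dt = dt_ref: multiplier exp(-1)
  C[3, 3] <- 13 * 0.01 * 0.5
  D1 <- saturation_step(D0, C, dom, sat, dt = 120)
  expect_equal(D1[3, 3] / D0[3, 3], exp(-1), tolerance = 1e-12)
  # non-cell nodes untouched
  expect_equal(D1[-13], D0[-13])

  # at/above the saturating concentration the diffusivity collapses
  C[3, 3] <- 13 * 0.01
  D2 <- saturation_step(D0, C, dom, sat, dt = 120)
  expect_lt(D2[3, 3], 1e-12)

  # exponent scales with dt: two half-steps equal one full step
  C[3, 3] <- 13 * 0.01 * 0.5
  Dh <- saturation_step(saturation_step(D0, C, dom, sat, dt = 60),
                        C, dom, sat, dt = 60)
  expect_equal(Dh[3, 3], D1[3, 3], tolerance = 1e-12)
})

test_that("exterior nodes hold the injection concentration at every frame", {
  dom <- small_domain()
  res <- run_simulation(dom, simulation_config(total_time = 6))
  for (C in res$concentration) {
    expect_true(all(C[dom$labels == 0L] == 13))
  }
  expect_true(all(res$concentration[[1]][dom$labels != 0L] == 0))
})

test_that("maximum principle and temporal monotonicity hold frame by frame", {
  gs <- small_grid()
  dom <- build_domain(gs)
  dom <- add_element(dom, "spheroid", c(150, 150), radius = 30)
  dom <- add_element(dom, "fibro_single", c(150, 210), radius = 11.5)
  dom <- init_diffusivity(dom, transport_config())
  res <- run_simulation(dom, simulation_config(total_time = 20))
  prev <- NULL
  for (C in res$concentration) {
    expect_true(all(C >= 0 & C <= 13))
    if (!is.null(prev)) expect_true(all(C - prev >= -1e-12))
    prev <- C
  }
})

test_that("cell diffusivity is non-increasing; medium diffusivity constant", {
  gs <- small_grid()
  dom <- add_element(build_domain(gs), "spheroid", c(150, 150), radius = 30)
  dom <- init_diffusivity(dom, transport_config())
  res <- run_simulation(dom, simulation_config(total_time = 20))
  cells <- dom$labels %in% lab[c("cancer", "fibroblast")]
  prev <- NULL
  for (D in res$diffusivity_frames) {
    expect_equal(D[!cells], dom$diffusivity[!cells])
    if (!is.null(prev)) expect_true(all(D[cells] - prev[cells] <= 0))
    prev <- D
  }
})

test_that("each diffusion step conserves mass up to the boundary flux", {
  gs <- grid_spec(20, 100, 40)
  dom <- build_domain(gs)
  dom$labels[10, 10] <- lab[["fibroblast"]]
  dom <- init_diffusivity(dom, transport_config())
  set.seed(7)
  C <- matrix(runif(400, 0, 13), 20, 20)
  C[dom$labels == 0L] <- 13
  dt <- stable_timestep(dom, 0.5)
  out <- diffuse_step(C, dom, dt)
  interior <- dom$labels != 0L
  dmass <- sum(out[interior]) - sum(C[interior])
  # net flux through interior/exterior faces, harmonic interfaces
  hmean <- function(a, b) ifelse(a + b > 0, 2 * a * b / (a + b), 0)
  flux <- 0
  for (idx in which(interior)) {
    i <- (idx - 1) %% 20 + 1; j <- (idx - 1) %/% 20 + 1
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > 20 || nb[2] < 1 || nb[2] > 20) next
      if (dom$labels[nb[1], nb[2]] != 0L) next
      flux <- flux + hmean(dom$diffusivity[i, j],
                           dom$diffusivity[nb[1], nb[2]]) *
        (C[nb[1], nb[2]] - C[i, j])
    }
  }
  expect_equal(dmass, dt / gs$dx^2 * flux, tolerance = 1e-12)
})

test_that("four-fold symmetric geometry stays symmetric every frame", {
  gs <- grid_spec(60, 300, 100)
  dom <- build_domain(gs)
  dom <- add_element(dom, "spheroid", c(150, 150), radius = 30)
  dom <- init_diffusivity(dom, transport_config())
  res <- run_simulation(dom, simulation_config(total_time = 10))
  for (C in res$concentration) {
    expect_lt(max(abs(C - rot90(C))), 1e-10)
  }
})

test_that("a closed fiber loop isolates its interior exactly", {
  gs <- grid_spec(60, 300, 120)
  dom <- build_domain(gs)
  dom <- paint_fiber_ring(dom, c(25, 36), c(25, 36))
  dom <- init_diffusivity(dom, transport_config())
  res <- run_simulation(dom, simulation_config(total_time = 30,
                                               saturation_enabled = FALSE))
  final <- res$concentration[[length(res$concentration)]]
  expect_true(all(final[26:35, 26:35] == 0))
  # while the outside has filled substantially
  expect_gt(mean(final[dom$labels == lab["medium"]]), 1)
})

test_that("halving the timestep leaves the final frame essentially unchanged", {
  gs <- small_grid()
  dom <- add_element(build_domain(gs), "spheroid", c(150, 150), radius = 30)
  dom <- init_diffusivity(dom, transport_config())
  dt0 <- 120 / ceiling(120 / stable_timestep(dom, 0.5))
  r1 <- run_simulation(dom, simulation_config(total_time = 30, dt = dt0))
  r2 <- run_simulation(dom, simulation_config(total_time = 30, dt = dt0 / 2))
  f1 <- r1$concentration[[length(r1$concentration)]]
  f2 <- r2$concentration[[length(r2$concentration)]]
  expect_lt(sqrt(sum((f1 - f2)^2) / sum(f2^2)), 1e-3)
})

test_that("overlarge or non-dividing timesteps are rejected", {
  dom <- small_domain()
  bound <- stable_timestep(dom, 1)
  expect_error(run_simulation(dom, simulation_config(dt = bound * 1.5)),
               class = "capsim_instability_error")
  expect_error(run_simulation(dom, simulation_config(dt = 17)),
               class = "capsim_config_error")
})
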