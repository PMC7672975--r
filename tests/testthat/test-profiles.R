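test_that("ROI means match brute-force node enumeration", {
  dom <- small_domain()
  res <- run_simulation(dom, simulation_config(total_time = 4,
                                               saturation_enabled = FALSE))
  # overwrite a frame with a linear ramp to decouple from the solver
  ax <- (seq_len(60) - 0.5) * 5
  ramp <- outer(ax, ax, function(x, y) 0.01 * x + 0.002 * y)
  res$concentration[[2]] <- ramp
  roi <- roi_spec("r1", 160, 140, 22)
  prof <- extract_profile(res, roi)
  # brute force average over enumerated member nodes
  sel <- outer(ax, ax, function(x, y) sqrt((x - 160)^2 + (y - 140)^2) <= 22)
  expect_equal(prof$value[2], mean(ramp[sel]))
  expect_equal(prof$area[1], sum(sel) * 25)

  # uniform frame value -> that value for any ROI
  res$concentration[[3]] <- matrix(7, 60, 60)
  expect_equal(extract_profile(res, roi)$value[3], 7)
})

test_that("an exterior ROI reads the injection concentration throughout", {
  dom <- small_domain()
  res <- run_simulation(dom, simulation_config(total_time = 6))
  prof <- extract_profile(res, roi_spec("out", 20, 20, 12))
  expect_true(all(prof$value == 13))
})

test_that("empty ROIs raise a geometry error", {
  dom <- small_domain()
  res <- run_simulation(dom, simulation_config(total_time = 2))
  expect_error(extract_profile(res, roi_spec("tiny", 151.2, 151.2, 0.5)),
               class = "capsim_geometry_error")
})

test_that("profile extraction is linear in the frame stack", {
  dom <- small_domain()
  res <- run_simulation(dom, simulation_config(total_time = 6,
                                               saturation_enabled = FALSE))
  roi <- roi_spec("r", 150, 150, 40)
  p1 <- extract_profile(res, roi)
  res2 <- res
  res2$concentration <- lapply(res$concentration, function(C) 3 * C + 1)
  p2 <- extract_profile(res2, roi)
  expect_equal(p2$value, 3 * p1$value + 1, tolerance = 1e-12)
})

test_that("normalization maps to [0, 1], is idempotent, and rejects constants", {
  p <- tibble::tibble(roi_id = "a", time_min = c(0, 2, 4),
                      value = c(2, 7, 12), normalized = FALSE)
  np <- normalize_profile(p)
  expect_equal(np$value, c(0, 0.5, 1))
  expect_true(all(np$normalized))
  expect_equal(normalize_profile(np)$value, np$value)
  pc <- tibble::tibble(roi_id = "c", time_min = c(0, 2), value = c(1, 1))
  expect_error(normalize_profile(pc),
               class = "capsim_degenerate_profile_error")
})

test_that("delay_time interpolates the threshold crossing", {
  step <- tibble::tibble(roi_id = "s", time_min = seq(0, 100, 2),
                         value = as.numeric(seq(0, 100, 2) >= 40))
  expect_equal(delay_time(step), 38 + 2 * 0.05)  # interpolated crossing
  start_high <- tibble::tibble(roi_id = "h", time_min = 0:9,
                               value = c(10, rep(1, 9)))
  expect_equal(delay_time(start_high), 0)
  flat0 <- tibble::tibble(roi_id = "z", time_min = 0:9, value = rep(0, 10))
  expect_warning(d <- delay_time(flat0))
  expect_true(is.na(d))
})

test_that("delay_time agrees with dense bisection on a Richards curve", {
  tt <- seq(0, 180, 2)
  p <- make_richards_profile(M = 1, beta = 0.05, gamma = 2, P0 = 0.001,
                             times = tt, noise_sigma = 0)
  got <- delay_time(p)
  # oracle: root of P(t) = 0.05 * max by bisection on the continuous curve
  f <- function(t) richards_curve(t, 1, 0.05, 2, 0.001) - 0.05 * max(p$value)
  lo <- 0; hi <- 180
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(got, (lo + hi) / 2, tolerance = 0.5)
  # antitone in the threshold fraction
  expect_gt(delay_time(p, 0.2), delay_time(p, 0.05))
})

test_that("log_phase_slope recovers a straight line and needs 3 points", {
  line <- tibble::tibble(roi_id = "l", time_min = 0:10,
                         value = 0.3 * (0:10))
  expect_equal(log_phase_slope(line), 0.3, tolerance = 1e-12)
  # adding a constant below max keeps the slope of in-band points
  sparse <- tibble::tibble(roi_id = "s", time_min = 0:3,
                           value = c(0, 0.5, 0.6, 1))
  expect_error(log_phase_slope(sparse),
               class = "capsim_insufficient_data_error")
})

test_that("log_phase_slope matches a 10x denser resampling of a Richards curve", {
  tt <- seq(0, 180, 2)
  p <- make_richards_profile(M = 1, beta = 0.05, gamma = 2, P0 = 0.001,
                             times = tt, noise_sigma = 0)
  dense <- make_richards_profile(M = 1, beta = 0.05, gamma = 2, P0 = 0.001,
                                 times = seq(0, 180, 0.2), noise_sigma = 0)
  expect_equal(log_phase_slope(p), log_phase_slope(dense), tolerance = 0.02)
})

test_that("deeper ROIs have longer delays on a simulated capsule", {
  dom <- build_domain(grid_spec(100, 1000, 350)) |> init_diffusivity()
  res <- run_simulation(dom, simulation_config(total_time = 120,
                                               saturation_enabled = FALSE,
                                               store_diffusivity = FALSE))
  depth <- seq(40, 310, length.out = 12)
  rois <- roi_spec(paste0("d", seq_along(depth)), 500 + 350 - depth,
                   rep(500, 12), rep(15, 12))
  prof <- extract_profile(res, rois)
  met <- profile_metrics(prof)
  met$depth <- depth[match(met$roi_id, paste0("d", seq_along(depth)))]
  expect_gt(cor(met$depth, met$delay_min, method = "spearman"), 0)
})
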