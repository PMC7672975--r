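# A compact calibration testbed: 60-node capsule, one central spheroid, a
# 30-minute challenge. Small enough that a full objective evaluation takes
# well under a second.
calib_bed <- function() {
  # off-center spheroid: the antibody front reaches it within the run, so
  # the profile actually responds to the saturation parameters
  dom <- add_element(build_domain(small_grid()), "spheroid", c(190, 150),
                     radius = 25)
  dom <- init_diffusivity(dom, transport_config())
  list(domain = dom,
       roi = roi_spec("sph", 190, 150, 25),
       sim = simulation_config(total_time = 30, store_diffusivity = FALSE))
}

test_that("rmse matches its definition and validates alignment", {
  expect_equal(rmse(c(0, 1), c(1, 1)), sqrt(0.5))
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(1, 2), c(2, 1)), rmse(c(2, 1), c(1, 2)))
  expect_error(rmse(1:3, 1:4), class = "capsim_alignment_error")
  expect_error(rmse(numeric(0), numeric(0)),
               class = "capsim_alignment_error")
})

test_that("the objective vanishes at the generating parameters and not at a = 0", {
  bed <- calib_bed()
  truth <- saturation_params(1, 1, 1)
  res <- run_simulation(bed$domain, bed$sim, truth)
  target <- extract_profile(res, bed$roi)
  obj <- saturation_objective(bed$domain, bed$roi, target, bed$sim)
  expect_lt(obj(c(1, 1, 1)), 1e-6)
  expect_gt(obj(c(1e-8, 1, 1)), 0.01)
})

test_that("the objective is memoized per parameter vector", {
  bed <- calib_bed()
  truth <- saturation_params(1, 1, 1)
  res <- run_simulation(bed$domain, bed$sim, truth)
  target <- extract_profile(res, bed$roi)
  obj <- saturation_objective(bed$domain, bed$roi, target, bed$sim)
  obj(c(1, 1, 1)); obj(c(1, 1, 1)); obj(c(2, 1, 1))
  counts <- attr(obj, "counts")()
  expect_equal(unname(counts["evaluations"]), 3)
  expect_equal(unname(counts["simulations"]), 2)
})

test_that("the truth is a local minimum along the a axis", {
  bed <- calib_bed()
  truth <- saturation_params(1, 1, 1)
  res <- run_simulation(bed$domain, bed$sim, truth)
  target <- extract_profile(res, bed$roi)
  obj <- saturation_objective(bed$domain, bed$roi, target, bed$sim)
  at_truth <- obj(c(1, 1, 1))
  expect_gt(obj(c(1.1, 1, 1)), at_truth)
  expect_gt(obj(c(0.9, 1, 1)), at_truth)
})

test_that("BFGS recovers the saturation parameters on noise-free targets", {
  bed <- calib_bed()
  truth <- saturation_params(1, 1, 1)
  res <- run_simulation(bed$domain, bed$sim, truth)
  target <- extract_profile(res, bed$roi)

  # from the truth: zero displacement
  fit0 <- fit_saturation(bed$domain, bed$roi, target, init = c(1, 1, 1),
                         sim = bed$sim)
  expect_lt(fit0$rmse, 1e-6)

  # from a perturbed start
  fit <- fit_saturation(bed$domain, bed$roi, target,
                        init = c(0.5, 1.5, 0.7), sim = bed$sim)
  expect_lte(fit$rmse, 0.01)
})

test_that("recovery holds across seeds on noise-free self-generated targets", {
  for (seed in c(2, 5, 9, 13, 17)) {
    gs <- small_grid()
    dom <- place_elements(build_domain(gs),
                          placement_config(n_spheroids = 1,
                                           spheroid_radius = 25,
                                           n_fibro_single = 4,
                                           n_fibro_cluster = 0),
                          seed = seed)
    dom <- init_diffusivity(dom, transport_config())
    roi <- roi_spec("sph", dom$spheroids$x, dom$spheroids$y,
                    dom$spheroids$radius)
    sim <- simulation_config(total_time = 30, store_diffusivity = FALSE)
    target <- extract_profile(run_simulation(dom, sim, saturation_params()),
                              roi)
    fit <- fit_saturation(dom, roi, target, init = c(0.7, 1.3, 0.8),
                          sim = sim)
    expect_lt(fit$rmse, 0.01)
  }
})

test_that("stronger saturation never raises the plateau at a deep cell ROI", {
  bed <- calib_bed()
  finals <- vapply(c(0.5, 1, 2, 4), function(a) {
    res <- run_simulation(bed$domain, bed$sim, saturation_params(a = a))
    tail(extract_profile(res, bed$roi)$value, 1)
  }, numeric(1))
  expect_true(all(diff(finals) <= 1e-12))
})

test_that("the per-cluster table reports RMSE under shared parameters", {
  bed <- calib_bed()
  rois <- dplyr::bind_rows(bed$roi, roi_spec("edge", 150, 235, 12))
  truth <- saturation_params(1, 1, 1)
  res <- run_simulation(bed$domain, bed$sim, truth)
  targets <- extract_profile(res, rois)
  fit <- fit_saturation(bed$domain, bed$roi,
                        targets[targets$roi_id == "sph", ],
                        init = c(1, 1, 1), sim = bed$sim,
                        report_rois = rois, targets = targets)
  expect_equal(nrow(fit$per_cluster), 2)
  expect_true(all(fit$per_cluster$rmse < 1e-6))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "n", "p"))
  expect_true(all(c("rmse", "evaluations") %in% names(glance(fit))))
})
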