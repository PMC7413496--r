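test_that("well-separated beads are all detected at their centres", {
  p <- bead_field_params(stack_shape = c(56, 160, 160), n_beads = 5,
                         min_separation = 2.5, poisson = FALSE,
                         read_noise_sd = 0, jitter_sd = 0, fwhm_cv = 0,
                         seed = 17)
  sim <- generate_bead_stack(p, psf_spec(0.41, 2.16))
  det <- detect_beads(sim$stack, min_separation = 2.5)
  det <- det[det$isolation_ok, ]
  expect_equal(nrow(det), 5)
  st <- sim$stack
  found <- cbind((det$z - 1) * st$axial_step,
                 (det$y - 1) * st$lateral_step,
                 (det$x - 1) * st$lateral_step)
  for (b in 1:5) {
    d <- sqrt(rowSums((found - matrix(sim$truth$centers[b, ], 5, 3,
                                      byrow = TRUE))^2))
    expect_lt(min(d), 0.3)  # within one voxel-ish of the true centre
  }
})

test_that("crowded beads are excluded in pairs and empty stacks yield none", {
  # two beads half the isolation distance apart: both flagged not isolated
  p <- clean_bead_params(stack_shape = c(56, 120, 120), seed = 23)
  sim1 <- generate_bead_stack(p, psf_spec(0.41, 2.16))
  st <- sim1$stack
  ctr <- sim1$truth$centers[1, ]
  # plant a second identical bead 1.25 um away laterally (min_sep 2.5)
  sh <- round(1.25 / st$lateral_step)
  v2 <- st$voxels
  v2[, , (1 + sh):dim(v2)[3]] <- v2[, , (1 + sh):dim(v2)[3]] +
    st$voxels[, , 1:(dim(v2)[3] - sh)]
  two <- image_stack(v2, st$lateral_step, st$axial_step)
  det <- detect_beads(two, min_separation = 2.5)
  expect_true(all(!det$isolation_ok))
  # uniform stack: no detections
  flat <- image_stack(array(7, c(10, 20, 20)), 0.05, 0.25)
  expect_equal(nrow(detect_beads(flat)), 0)
})

test_that("profiles are centred, uniformly spaced, and bounded by the stack", {
  sim <- generate_bead_stack(clean_bead_params(seed = 5),
                             psf_spec(0.41, 2.16))
  det <- detect_beads(sim$stack)
  pv <- c(det$z[1], det$y[1], det$x[1])
  pz <- extract_profile(sim$stack, pv, "axial_z")
  expect_equal(pz$position[which.max(pz$value)], 0)
  expect_equal(unique(round(diff(pz$position), 10)), 0.25)
  px <- extract_profile(sim$stack, pv, "lateral_x")
  expect_equal(unique(round(diff(px$position), 10)), 0.05)
  expect_equal(half_max_width(pz), 2.16, tolerance = 0.05 / 2.16)
  expect_error(extract_profile(sim$stack, pv, "axial_z", half_width = 50),
               "window")
})

test_that("Gaussian fits recover exact parameters on clean profiles", {
  prof <- gaussian_profile(sigma = 1, A = 10, b = 10)
  fit <- fit_gaussian(prof, "free_center")
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$offset, 10, tolerance = 1e-6)
  expect_lt(fit$fit_rmse, 1e-8)
  expect_true(fit$reliable)
  expect_equal(unname(coef(fit)["sigma"]), 1, tolerance = 1e-6)
  expect_error(fit_gaussian(gaussian_profile(by = 2)), "7 samples")
  edge <- data.frame(position = 0:9, value = 10:1 + 0)
  expect_error(fit_gaussian(edge), "edge")
})

test_that("pinning the centre off-peak biases the width upward", {
  # sampled off-centre by 0.3 of a step: the fixed-centre model is wrong
  prof <- gaussian_profile(sigma = 1, mu = 0.3 * 0.25, by = 0.25)
  free <- fit_gaussian(prof, "free_center")
  fixed <- fit_gaussian(prof, "fixed_center")
  expect_gt(fixed$fwhm, free$fwhm)
  expect_gte(fixed$fit_rmse, free$fit_rmse)  # free fit is a superset model
  expect_equal(free$center, 0.075, tolerance = 1e-4)
})

test_that("fitted and half-max-crossing widths agree on noiseless beads", {
  for (fw in list(c(0.41, 2.16), c(0.50, 2.87), c(0.58, 4.51))) {
    sim <- generate_bead_stack(clean_bead_params(seed = 29),
                               psf_spec(fw[1], fw[2]))
    det <- detect_beads(sim$stack)
    pv <- c(det$z[1], det$y[1], det$x[1])
    for (ax in c("lateral_x", "axial_z")) {
      prof <- extract_profile(sim$stack, pv, ax)
      fit <- fit_gaussian(prof, "free_center")
      expect_equal(fit$fwhm, half_max_width(prof, baseline = 0),
                   tolerance = 0.005)
    }
  }
})

test_that("measure_bead recovers the generator ground truth", {
  sim <- generate_bead_stack(clean_bead_params(seed = 41),
                             psf_spec(0.41, 2.16))
  det <- detect_beads(sim$stack)
  m <- measure_bead(sim$stack, det[1, ], "free_center")
  expect_equal(m$fwhm_xy, 0.41, tolerance = 0.01)
  expect_equal(m$fwhm_z, 2.16, tolerance = 0.01)
  expect_true(m$reliable)
  # isotropic bead: both axes agree
  iso <- generate_bead_stack(clean_bead_params(seed = 43),
                             psf_spec(1.2, 1.2))
  deti <- detect_beads(iso$stack)
  mi <- measure_bead(iso$stack, deti[1, ], "free_center")
  expect_equal(mi$fwhm_xy, mi$fwhm_z, tolerance = 0.02)
  # jittered bead in fixed-centre mode still yields finite widths
  pj <- bead_field_params(n_beads = 1, jitter_sd = 0.1, seed = 47)
  simj <- generate_bead_stack(pj, psf_spec(0.41, 2.16))
  detj <- detect_beads(simj$stack, smooth_fwhm = psf_spec(0.41, 2.16))
  mj <- measure_bead(simj$stack, detj[which.max(detj$peak_intensity), ],
                     "fixed_center")
  expect_true(is.finite(mj$fwhm_xy) && is.finite(mj$fwhm_z))
})

test_that("recovered axial width grows with depth in both fill modes", {
  for (fm in c("overfill", "underfill")) {
    means <- vapply(c(100, 200, 300), function(d) {
      psf <- psf_preset(imaging_condition(fm, depth = d))
      vals <- vapply(1:5, function(b) {
        p <- bead_field_params(n_beads = 1, fwhm_cv = 0,
                               seed = 6000 + 100 * d + b)
        sim <- generate_bead_stack(p, psf)
        det <- detect_beads(sim$stack, smooth_fwhm = psf)
        det <- det[det$isolation_ok, ]
        measure_bead(sim$stack, det[which.max(det$peak_intensity), ],
                     "free_center")$fwhm_z
      }, numeric(1))
      mean(vals)
    }, numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("condition summaries use mean and s.e.m. conventions", {
  s <- summarize_condition(data.frame(fwhm_xy = c(1, 2, 3),
                                      fwhm_z = c(2, 2, 2)))
  expect_equal(s$mean_fwhm_xy, 2)
  expect_equal(s$sem_fwhm_xy, 0.5774, tolerance = 1e-4)
  expect_equal(s$mean_fwhm_z, 2)
  expect_equal(s$sem_fwhm_z, 0)
  one <- summarize_condition(data.frame(fwhm_xy = 1, fwhm_z = 2))
  expect_true(is.na(one$sem_fwhm_xy))  # undefined, not zero
  expect_error(summarize_condition(data.frame(fwhm_xy = numeric(0),
                                              fwhm_z = numeric(0))),
               "no reliable")
  # unreliable rows are dropped
  s2 <- summarize_condition(data.frame(fwhm_xy = c(1, 100), fwhm_z = c(2, 100),
                                       reliable = c(TRUE, FALSE)))
  expect_equal(s2$n_beads, 1)
})

test_that("expansion ratios reproduce the printed deep/shallow comparison", {
  deep <- summarize_condition(data.frame(fwhm_xy = 0.53, fwhm_z = 4.14))
  shallow <- summarize_condition(data.frame(fwhm_xy = 0.41, fwhm_z = 2.16))
  r <- expansion_ratio(deep, shallow)
  expect_equal(r$lateral, 1.29)
  expect_equal(r$axial, 1.92)
  expect_equal(r$lateral_1dp, 1.3)
  expect_equal(r$axial_1dp, 1.9)
  same <- expansion_ratio(shallow, shallow)
  expect_equal(c(same$lateral, same$axial), c(1, 1))
})
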