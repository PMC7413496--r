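test_that("a noise-free bead peaks at the voxel nearest its true centre", {
  sim <- generate_bead_stack(clean_bead_params(seed = 3),
                             psf_spec(0.41, 2.16))
  st <- sim$stack
  peak <- which(st$voxels == max(st$voxels), arr.ind = TRUE)[1, ]
  ctr <- sim$truth$centers[1, ]
  expect_equal(unname(peak[1]), round(ctr["z"] / st$axial_step) + 1,
               ignore_attr = TRUE)
  expect_equal(unname(peak[2]), round(ctr["y"] / st$lateral_step) + 1,
               ignore_attr = TRUE)
  expect_equal(unname(peak[3]), round(ctr["x"] / st$lateral_step) + 1,
               ignore_attr = TRUE)
})

test_that("rendered profiles match the requested widths within 1%", {
  for (fw in list(c(0.41, 2.16), c(0.58, 4.51))) {
    sim <- generate_bead_stack(clean_bead_params(seed = 9),
                               psf_spec(fw[1], fw[2]))
    det <- detect_beads(sim$stack)
    pv <- c(det$z[1], det$y[1], det$x[1])
    wz <- half_max_width(extract_profile(sim$stack, pv, "axial_z"),
                         baseline = 0)
    wx <- half_max_width(extract_profile(sim$stack, pv, "lateral_x"),
                         baseline = 0)
    expect_equal(wz, fw[2], tolerance = 0.01)
    expect_equal(wx, fw[1], tolerance = 0.01)
  }
})

test_that("1.0-um beads render wider than the nominal axial width", {
  psf <- psf_spec(0.41, 2.16)
  sim <- generate_bead_stack(clean_bead_params(bead_diameter = 1.0,
                                               min_separation = 2, seed = 4),
                             psf)
  det <- detect_beads(sim$stack)
  pv <- c(det$z[1], det$y[1], det$x[1])
  wz <- half_max_width(extract_profile(sim$stack, pv, "axial_z"),
                       baseline = 0)
  wx <- half_max_width(extract_profile(sim$stack, pv, "lateral_x"),
                       baseline = 0)
  expect_gt(wz, psf$fwhm_axial)
  expect_gt(wx, psf$fwhm_lateral)
})

test_that("bead stacks are bit-reproducible under a fixed seed", {
  p <- bead_field_params(n_beads = 2, min_separation = 1.5, seed = 42)
  a <- generate_bead_stack(p, psf_spec(0.41, 2.16))
  b <- generate_bead_stack(p, psf_spec(0.41, 2.16))
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth$centers, b$truth$centers)
})

test_that("infeasible bead packing fails after bounded retries", {
  p <- bead_field_params(stack_shape = c(40, 44, 44), n_beads = 30,
                         min_separation = 2, seed = 1)
  expect_error(generate_bead_stack(p, psf_spec(0.41, 2.16)),
               "could not place|too small")
})

test_that("total photon count scales linearly with peak brightness", {
  totals <- function(peak) {
    mean(vapply(1:100, function(s) {
      p <- bead_field_params(stack_shape = c(24, 24, 24), n_beads = 1,
                             peak_photons = peak, read_noise_sd = 0,
                             jitter_sd = 0, fwhm_cv = 0,
                             margin_lateral = 0.5, margin_axial = 2,
                             seed = 1000 + s)
      sum(generate_bead_stack(p, psf_spec(0.41, 2.16))$stack$voxels)
    }, numeric(1)))
  }
  t1 <- totals(200)
  t4 <- totals(800)
  expect_equal(t4 / t1, 4, tolerance = 0.02)
})

test_that("structure stacks degrade contrast as the focal volume grows", {
  p <- structure_field_params(seed = 21, poisson = FALSE, read_noise_sd = 0)
  sharp <- generate_structure_stack(p, psf_spec(0.41, 2.16))
  blurry <- generate_structure_stack(p, psf_spec(0.58, 4.51))
  mid <- ceiling(dim(sharp$stack)[1] / 2)
  expect_gt(brenner_gradient(sharp$stack$voxels[mid, , ]),
            brenner_gradient(blurry$stack$voxels[mid, , ]))
  # the blur-free reference is sharper still
  expect_gt(brenner_gradient(sharp$reference$voxels[mid, , ]),
            brenner_gradient(sharp$stack$voxels[mid, , ]))
})

test_that("a structure-free field is pure background noise", {
  p <- structure_field_params(n_filaments = 0, background = 5, seed = 8)
  sim <- generate_structure_stack(p, psf_spec(0.41, 2.16))
  expect_equal(mean(sim$stack$voxels), 5, tolerance = 0.05)
  expect_equal(max(sim$reference$voxels), 0)
})

test_that("a noise-free filament survives as a bright connected line", {
  p <- structure_field_params(n_filaments = 1, n_spines = 0,
                              background = 0, poisson = FALSE,
                              read_noise_sd = 0, seed = 13)
  sim <- generate_structure_stack(p, psf_spec(0.41, 2.16))
  mip <- apply(sim$stack$voxels, c(2, 3), max)
  expect_gt(max(mip), 0)
  labels <- focalmetry:::label_components(mip > 0.5 * max(mip), 8)
  expect_equal(max(labels), 1)  # one connected bright structure
})

test_that("calcium movies honour their event ground truth", {
  # a single 30-pixel event, no noise: exactly one ROI of that area
  base <- calcium_movie_params(n_cells = 1, event_rate = 0, n_distractors = 0,
                               noise_sd = 0, poisson = FALSE, seed = 2)
  sim <- generate_calcium_movie(base)
  expect_equal(nrow(sim$truth), 0)
  act <- quiet_extract(sim$movie, sim$vessel_mask)
  expect_length(act$rois, 0)
})

test_that("event pixel sets lie inside cells and respect area classes", {
  p <- calcium_movie_params(n_cells = 3, event_rate = 10, n_distractors = 2,
                            seed = 31)
  sim <- generate_calcium_movie(p)
  tr <- sim$truth
  expect_true(all(tr$area[!tr$is_distractor] >= 21))
  expect_true(all(tr$area[tr$is_distractor] <= 20))
  vessel_px <- which(sim$vessel_mask)
  for (px in tr$pixels)
    expect_length(intersect(px, vessel_px), 0)
})
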