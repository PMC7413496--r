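test_that("pupil diameter follows 2 NA f_tube / M and rejects bad specs", {
  expect_equal(pupil_diameter(objective_spec(25, 1.05, 180)), 15.12)
  expect_equal(pupil_diameter(objective_spec(1, 0.5, 1)), 1.0)
  # linear in NA and f_tube, inverse in magnification
  set.seed(11)
  for (i in 1:20) {
    M <- runif(1, 4, 100); na <- runif(1, 0.1, 1.4); f <- runif(1, 100, 200)
    d <- pupil_diameter(objective_spec(M, na, f))
    expect_equal(pupil_diameter(objective_spec(M, 2 * na / 2, f)), d)
    expect_equal(pupil_diameter(objective_spec(M, na, 2 * f)), 2 * d)
    expect_equal(pupil_diameter(objective_spec(2 * M, na, f)), d / 2)
  }
  expect_error(objective_spec(-25, 1.05), "magnification")
  expect_error(objective_spec(25, 1.8), "numerical_aperture")
  expect_error(objective_spec(25, 1.05, 0), "tube_focal_length")
})

test_that("fill fraction reproduces the printed overfill percentage", {
  obj <- objective_spec(25, 1.05, 180)
  f_over <- fill_fraction(beam_config(17.4), obj)
  expect_equal(round(100 * as.numeric(f_over), 1), 115.1)
  expect_equal(attr(f_over, "classification"), "overfill")
  f_eq <- fill_fraction(beam_config(pupil_diameter(obj)), obj)
  expect_equal(as.numeric(f_eq), 1.0)
  expect_equal(attr(f_eq, "classification"), "underfill")
  f_under <- fill_fraction(beam_config(10.8), obj)
  expect_equal(as.numeric(f_under), 0.714, tolerance = 1e-3)
  expect_equal(attr(f_under, "classification"), "underfill")
})

test_that("focal-volume presets anchor on measured depths and interpolate", {
  p100 <- psf_preset(imaging_condition("overfill", depth = 100))
  expect_equal(c(p100$fwhm_lateral, p100$fwhm_axial), c(0.41, 2.16))
  p300u <- psf_preset(imaging_condition("underfill", depth = 300))
  expect_equal(c(p300u$fwhm_lateral, p300u$fwhm_axial), c(0.58, 4.51))
  p150 <- psf_preset(imaging_condition("overfill", depth = 150))
  expect_equal(c(p150$fwhm_lateral, p150$fwhm_axial), c(0.405, 2.245))
  # outside the anchors: error unless extrapolation is requested
  expect_error(psf_preset(imaging_condition("overfill", depth = 350)),
               "extrapolate")
  p350 <- psf_preset(imaging_condition("overfill", depth = 350),
                     extrapolate = TRUE)
  expect_gt(p350$fwhm_axial, 4.14)
  # axial growth from 200 to 300 um in both fill modes
  for (fm in c("overfill", "underfill")) {
    z200 <- psf_preset(imaging_condition(fm, depth = 200))$fwhm_axial
    z300 <- psf_preset(imaging_condition(fm, depth = 300))$fwhm_axial
    expect_gt(z300, z200)
  }
  # axial elongation holds across the whole preset grid
  for (fm in c("overfill", "underfill"))
    for (d in seq(100, 300, by = 25)) {
      p <- psf_preset(imaging_condition(fm, depth = d))
      expect_gte(p$fwhm_axial, p$fwhm_lateral)
    }
})

test_that("RI-mismatch model reduces to the preset at its optimum", {
  cond_opt <- imaging_condition("overfill", 1.355, 300)
  expect_equal(unclass(psf_model(cond_opt)),
               unclass(psf_preset(cond_opt)))
  # zero gain: preset for any RI
  cond <- imaging_condition("overfill", 1.33, 300)
  pars0 <- aberration_params(axial_mismatch_gain = 0,
                             lateral_mismatch_gain = 0)
  expect_equal(unclass(psf_model(cond, pars0)), unclass(psf_preset(cond)))
  # axial gain chosen so the inflation factor is exactly 1.2
  gain <- 0.2 / (300 * (1.33 - 1.355)^2)
  pars <- aberration_params(axial_mismatch_gain = gain,
                            lateral_mismatch_gain = 0)
  expect_equal(psf_model(cond, pars)$fwhm_axial, 4.14 * 1.2)
})

test_that("modelled axial width is minimised at the RI nearest the optimum", {
  ri_grid <- seq(1.33, 1.37, by = 0.01)
  for (fm in c("overfill", "underfill"))
    for (d in c(100, 200, 300)) {
      axial <- vapply(ri_grid, function(n)
        psf_model(imaging_condition(fm, n, d))$fwhm_axial, numeric(1))
      expect_equal(ri_grid[which.min(axial)],
                   ri_grid[which.min(abs(ri_grid - 1.355))])
      # strictly increasing with mismatch magnitude on either side
      expect_true(all(diff(axial[ri_grid >= 1.36]) > 0))
      expect_true(all(diff(axial[ri_grid <= 1.35]) < 0))
      lat <- vapply(ri_grid, function(n)
        psf_model(imaging_condition(fm, n, d))$fwhm_lateral, numeric(1))
      expect_true(all(axial >= lat))
    }
})

test_that("named presets carry the standard and enhanced configurations", {
  s <- condition_preset("S")
  expect_equal(s$fill_mode, "overfill")
  expect_equal(s$immersion_ri, 1.33)
  e <- condition_preset("E", depth = 300)
  expect_equal(e$fill_mode, "underfill")
  expect_equal(e$immersion_ri, 1.36)
  expect_equal(e$depth, 300)
})
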