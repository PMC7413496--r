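# Objective/beam geometry, per-condition focal-volume presets, and the
# phenomenological depth x RI-mismatch model used by the synthetic generator.

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # FWHM = 2*sqrt(2 ln 2) * sigma

#' Objective lens specification
#'
#' Describes an infinity-corrected objective by its magnification, numerical
#' aperture and tube-lens focal length. The tube focal length defaults to
#' 180 mm (Olympus convention).
#'
#' @param magnification Dimensionless magnification, > 0.
#' @param numerical_aperture Numerical aperture, in (0, 1.7).
#' @param tube_focal_length Tube-lens focal length in mm, > 0.
#' @return An object of class `objective_spec`.
#' @examples
#' obj <- objective_spec(25, 1.05)
#' pupil_diameter(obj)
#' @export
objective_spec <- function(magnification, numerical_aperture,
                           tube_focal_length = 180) {
  stopifnot(is.numeric(magnification), is.numeric(numerical_aperture),
            is.numeric(tube_focal_length))
  if (!is.finite(magnification) || magnification <= 0)
    stop("invalid objective specification: magnification must be > 0",
         call. = FALSE)
  if (!is.finite(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture >= 1.7)
    stop("invalid objective specification: numerical_aperture must be in (0, 1.7)",
         call. = FALSE)
  if (!is.finite(tube_focal_length) || tube_focal_length <= 0)
    stop("invalid objective specification: tube_focal_length must be > 0",
         call. = FALSE)
  structure(list(magnification = magnification,
                 numerical_aperture = numerical_aperture,
                 tube_focal_length = tube_focal_length),
            class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("Objective: %gx / NA %g (f_tube %g mm), pupil %.2f mm\n",
              x$magnification, x$numerical_aperture, x$tube_focal_length,
              pupil_diameter(x)))
  invisible(x)
}

#' Excitation beam configuration
#'
#' @param beam_diameter Beam diameter at the entrance-pupil plane, mm, > 0.
#' @param fill_mode `"overfill"` or `"underfill"`.
#' @return An object of class `beam_config`.
#' @export
beam_config <- function(beam_diameter, fill_mode = c("overfill", "underfill")) {
  fill_mode <- match.arg(fill_mode)
  if (!is.numeric(beam_diameter) || !is.finite(beam_diameter) ||
      beam_diameter <= 0)
    stop("beam_diameter must be a positive finite number", call. = FALSE)
  structure(list(beam_diameter = beam_diameter, fill_mode = fill_mode),
            class = "beam_config")
}

#' Imaging condition
#'
#' Bundles the experiment axes that determine the focal volume: pupil fill
#' mode, immersion-liquid refractive index, and imaging depth below the
#' tissue surface.
#'
#' @param fill_mode `"overfill"` or `"underfill"`.
#' @param immersion_ri Immersion refractive index, in \[1.30, 1.40\].
#' @param depth Imaging depth in micrometres, >= 0.
#' @return An object of class `imaging_condition`.
#' @seealso [condition_preset()] for the named standard/enhanced conditions.
#' @export
imaging_condition <- function(fill_mode = c("overfill", "underfill"),
                              immersion_ri = 1.33, depth = 100) {
  fill_mode <- match.arg(fill_mode)
  if (!is.numeric(immersion_ri) || immersion_ri < 1.30 || immersion_ri > 1.40)
    stop("immersion_ri must lie in [1.30, 1.40]", call. = FALSE)
  if (!is.numeric(depth) || !is.finite(depth) || depth < 0)
    stop("depth must be >= 0 (micrometres)", call. = FALSE)
  structure(list(fill_mode = fill_mode, immersion_ri = immersion_ri,
                 depth = depth),
            class = "imaging_condition")
}

#' @export
print.imaging_condition <- function(x, ...) {
  cat(sprintf("Imaging condition: %s, n = %.3f, depth = %g um\n",
              x$fill_mode, x$immersion_ri, x$depth))
  invisible(x)
}

#' Named imaging-condition presets
#'
#' `"S"` is the standard configuration (overfilled pupil, water immersion,
#' n = 1.33); `"E"` is the enhanced deep-imaging configuration (underfilled
#' pupil, immersion adjusted to n = 1.36).
#'
#' @param name `"S"` or `"E"`.
#' @param depth Imaging depth in micrometres.
#' @return An [imaging_condition()].
#' @export
condition_preset <- function(name = c("S", "E"), depth = 100) {
  name <- match.arg(name)
  switch(name,
         S = imaging_condition("overfill",  1.33, depth),
         E = imaging_condition("underfill", 1.36, depth))
}

#' Focal-volume width specification
#'
#' Lateral and axial full widths at half maximum of the (effective) focal
#' volume. Two-photon focal volumes are axially elongated, so the axial
#' width must not be smaller than the lateral one.
#'
#' @param fwhm_lateral Lateral FWHM, micrometres, > 0.
#' @param fwhm_axial Axial FWHM, micrometres, >= `fwhm_lateral`.
#' @return An object of class `psf_spec`.
#' @export
psf_spec <- function(fwhm_lateral, fwhm_axial) {
  if (!is.numeric(fwhm_lateral) || !is.numeric(fwhm_axial) ||
      !is.finite(fwhm_lateral) || !is.finite(fwhm_axial))
    stop("FWHMs must be finite numbers", call. = FALSE)
  if (fwhm_lateral <= 0)
    stop("fwhm_lateral must be > 0", call. = FALSE)
  if (fwhm_axial < fwhm_lateral)
    stop("fwhm_axial must be >= fwhm_lateral (axially elongated focal volume)",
         call. = FALSE)
  structure(list(fwhm_lateral = fwhm_lateral, fwhm_axial = fwhm_axial),
            class = "psf_spec")
}

#' @export
print.psf_spec <- function(x, ...) {
  cat(sprintf("PSF: FWHM_xy = %.3f um, FWHM_z = %.3f um\n",
              x$fwhm_lateral, x$fwhm_axial))
  invisible(x)
}

#' Entrance-pupil diameter of an objective
#'
#' For an infinity-corrected objective the entrance-pupil (back-aperture)
#' diameter is `2 * NA * f_tube / M`.
#'
#' @param objective An [objective_spec()].
#' @return Pupil diameter in mm.
#' @examples
#' pupil_diameter(objective_spec(25, 1.05, 180))  # 15.12 mm
#' @export
pupil_diameter <- function(objective) {
  stopifnot(inherits(objective, "objective_spec"))
  2 * objective$numerical_aperture * objective$tube_focal_length /
    objective$magnification
}

#' Pupil fill fraction of an excitation beam
#'
#' Ratio of the beam diameter at the entrance-pupil plane to the pupil
#' diameter. Fractions above 1 are classified as overfill, at or below 1 as
#' underfill (attribute `"classification"` of the result).
#'
#' @param beam A [beam_config()].
#' @param objective An [objective_spec()].
#' @return Dimensionless fraction with attribute `classification`.
#' @examples
#' fill_fraction(beam_config(17.4), objective_spec(25, 1.05))  # 1.151
#' @export
fill_fraction <- function(beam, objective) {
  stopifnot(inherits(beam, "beam_config"))
  f <- beam$beam_diameter / pupil_diameter(objective)
  attr(f, "classification") <- if (f > 1) "overfill" else "underfill"
  f
}

preset_table_path <- function() {
  system.file("extdata", "fwhm_presets.tsv", package = "focalmetry",
              mustWork = TRUE)
}

#' Measured focal-volume preset table
#'
#' Per-condition mean effective FWHMs measured with 200-nm beads at depths
#' of 100, 200 and 300 um under overfilled and underfilled pupils, together
#' with the number of beads each mean is based on.
#'
#' @return A data.frame with columns `fill_mode`, `depth_um`, `fwhm_xy_um`,
#'   `fwhm_z_um`, `n_beads`.
#' @export
fwhm_presets <- function() {
  utils::read.delim(preset_table_path(), stringsAsFactors = FALSE)
}

# Linear interpolation with optional linear extrapolation from the two
# nearest anchors.
interp_anchor <- function(x, y, x0, extrapolate) {
  if (x0 >= min(x) && x0 <= max(x))
    return(stats::approx(x, y, xout = x0)$y)
  if (!extrapolate)
    stop("depth ", x0, " um is outside the anchored range [", min(x), ", ",
         max(x), "] um; set extrapolate = TRUE to extend linearly",
         call. = FALSE)
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (x0 < x[1]) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    y[1] + slope * (x0 - x[1])
  } else {
    n <- length(x)
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    y[n] + slope * (x0 - x[n])
  }
}

#' Preset focal-volume widths for an imaging condition
#'
#' Looks up the measured mean FWHM pair for the condition's fill mode and
#' depth, interpolating linearly in depth between the anchored depths
#' (100, 200, 300 um). Depths outside the anchored range raise an error
#' unless `extrapolate = TRUE`.
#'
#' @param condition An [imaging_condition()].
#' @param extrapolate Allow linear extrapolation beyond the anchored depths.
#' @return A [psf_spec()].
#' @examples
#' psf_preset(imaging_condition("overfill", depth = 100))  # 0.41 / 2.16 um
#' @export
psf_preset <- function(condition, extrapolate = FALSE) {
  stopifnot(inherits(condition, "imaging_condition"))
  tab <- fwhm_presets()
  tab <- tab[tab$fill_mode == condition$fill_mode, ]
  psf_spec(
    interp_anchor(tab$depth_um, tab$fwhm_xy_um, condition$depth, extrapolate),
    interp_anchor(tab$depth_um, tab$fwhm_z_um,  condition$depth, extrapolate))
}

#' Refractive-index-mismatch aberration model parameters
#'
#' Parameters of the phenomenological model that inflates the preset focal
#' volume when the immersion refractive index departs from the optimum.
#' The inflation is quadratic in the mismatch and proportional to depth;
#' it is a simulator device, not diffraction physics. Default gains give a
#' 1.3-fold axial and 1.1-fold lateral inflation at a mismatch of 0.025 and
#' 300 um depth.
#'
#' @param optimal_ri Immersion RI at which the focal volume is smallest.
#' @param axial_mismatch_gain Axial gain, 1/(um RI^2), >= 0.
#' @param lateral_mismatch_gain Lateral gain, same units, >= 0.
#' @return An object of class `aberration_params`.
#' @export
aberration_params <- function(optimal_ri = 1.355,
                              axial_mismatch_gain = 1.6,
                              lateral_mismatch_gain = 1.6 / 3) {
  if (axial_mismatch_gain < 0 || lateral_mismatch_gain < 0)
    stop("mismatch gains must be >= 0", call. = FALSE)
  structure(list(optimal_ri = optimal_ri,
                 axial_mismatch_gain = axial_mismatch_gain,
                 lateral_mismatch_gain = lateral_mismatch_gain),
            class = "aberration_params")
}

#' Modelled focal-volume widths under refractive-index mismatch
#'
#' Multiplies the depth-interpolated preset widths by
#' `1 + gain * depth * (n - optimal_ri)^2` per axis. At the optimal RI (or
#' with zero gains) the preset is returned exactly; for fixed depth the
#' axial width increases strictly with the mismatch magnitude.
#'
#' @param condition An [imaging_condition()].
#' @param params An [aberration_params()].
#' @param extrapolate Passed to [psf_preset()].
#' @return A [psf_spec()].
#' @export
psf_model <- function(condition, params = aberration_params(),
                      extrapolate = FALSE) {
  stopifnot(inherits(condition, "imaging_condition"),
            inherits(params, "aberration_params"))
  base <- psf_preset(condition, extrapolate = extrapolate)
  dn2 <- (condition$immersion_ri - params$optimal_ri)^2
  psf_spec(
    base$fwhm_lateral * (1 + params$lateral_mismatch_gain * condition$depth * dn2),
    base$fwhm_axial   * (1 + params$axial_mismatch_gain   * condition$depth * dn2))
}
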