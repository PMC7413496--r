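# Bead detection and FWHM metrology: locate isolated beads in a 3D stack,
# pull single-voxel-wide axial/lateral intensity profiles through each peak,
# fit 1D Gaussians and summarise per condition.
#
# Protocol notes: lateral FWHM is measured along x only and axial along z
# (1D profiles, no 3D fit and no averaging over y). "In vitro" measurements
# use a free Gaussian centre; "in vivo" measurements pin the centre to the
# peak voxel (the fixed-centre presumption used for blurry, motion-affected
# beads). The mode is always explicit, never auto-selected.

# Neighbourhood maximum over the 3x3x3 neighbourhood (excluding self),
# computed by shifting; borders padded with -Inf.
shift_array <- function(arr, dz, dy, dx) {
  d <- dim(arr)
  out <- array(-Inf, dim = d)
  zs <- seq_len(d[1]); ys <- seq_len(d[2]); xs <- seq_len(d[3])
  z_to <- zs[zs + dz >= 1 & zs + dz <= d[1]]
  y_to <- ys[ys + dy >= 1 & ys + dy <= d[2]]
  x_to <- xs[xs + dx >= 1 & xs + dx <= d[3]]
  out[z_to, y_to, x_to] <- arr[z_to + dz, y_to + dy, x_to + dx]
  out
}

# Light separable [1,2,1]/4 smoothing used for peak *detection* only;
# profiles for measurement are always taken from the raw stack. Without it,
# shot noise fragments a single bead into neighbouring duplicate maxima
# that the isolation rule would then discard in pairs. Border weights are
# renormalised so a constant stack stays exactly constant.
smooth121 <- function(arr) {
  ones <- array(1, dim = dim(arr))
  for (ax in 1:3) {
    minus <- shift_array(arr, -(ax == 1), -(ax == 2), -(ax == 3))
    plus <- shift_array(arr, (ax == 1), (ax == 2), (ax == 3))
    wminus <- is.finite(minus) + 0
    wplus <- is.finite(plus) + 0
    minus[!is.finite(minus)] <- 0
    plus[!is.finite(plus)] <- 0
    arr <- (minus + 2 * arr + plus) / (wminus + 2 * ones + wplus)
  }
  arr
}

#' Detect candidate beads as local 3D maxima
#'
#' Finds local maxima of the (lightly smoothed) stack above an intensity
#' floor. Every candidate is returned; candidates closer than
#' `min_separation` (um, 3D distance) to another candidate, or closer than
#' `border_margin` to any stack face, are flagged `isolation_ok = FALSE`
#' and should be excluded from measurement. Intensity ties within a
#' neighbourhood are broken by ascending (z, y, x) scan order.
#'
#' @param stack An [image_stack()].
#' @param intensity_floor Minimum raw peak intensity; `NULL` uses 25% of
#'   the stack maximum.
#' @param min_separation Minimum pairwise distance between isolated
#'   detections, um.
#' @param border_margin Minimum distance from any stack face, um.
#' @param merge_radius Candidates closer than this (um) are treated as
#'   duplicate maxima of one bead and merged, keeping the brightest;
#'   defaults to half of `min_separation`, below which two genuine beads
#'   could not satisfy the isolation rule anyway. Noise on a broad peak
#'   otherwise fragments one bead into a pair of mutual exclusions.
#' @param smooth_fwhm Optional [psf_spec()] (or `c(lateral, axial)` in um)
#'   giving the expected spot widths; when supplied, detection smooths with
#'   a matched Gaussian kernel of half those widths, which suppresses
#'   duplicate noise maxima on broad peaks. Without it a light 1-2-1
#'   kernel is used. Detection only — measurements always read the raw
#'   stack.
#' @return A data.frame with columns `z`, `y`, `x` (voxel indices),
#'   `peak_intensity` and `isolation_ok`.
#' @export
detect_beads <- function(stack, intensity_floor = NULL, min_separation = 2,
                         border_margin = 1,
                         merge_radius = min_separation / 2,
                         smooth_fwhm = NULL) {
  stopifnot(inherits(stack, "image_stack"), min_separation > 0)
  raw <- stack$voxels
  if (is.null(intensity_floor)) intensity_floor <- 0.25 * max(raw)
  sm <- if (is.null(smooth_fwhm)) {
    smooth121(raw)
  } else {
    fw <- if (inherits(smooth_fwhm, "psf_spec"))
      c(smooth_fwhm$fwhm_lateral, smooth_fwhm$fwhm_axial) else smooth_fwhm
    sig_lat <- fw[1] / FWHM_SIGMA / 2
    sig_axi <- fw[2] / FWHM_SIGMA / 2
    gauss_blur_3d(raw, sig_axi / stack$axial_step,
                  sig_lat / stack$lateral_step,
                  sig_lat / stack$lateral_step)
  }
  neigh <- array(-Inf, dim = dim(sm))
  neigh_min <- array(Inf, dim = dim(sm))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    sh <- shift_array(sm, dz, dy, dx)
    neigh <- pmax(neigh, sh)
    shmin <- sh
    shmin[!is.finite(shmin)] <- Inf
    neigh_min <- pmin(neigh_min, shmin)
  }
  # maxima: at least as large as every neighbour and strictly above the
  # smallest one (a fully flat neighbourhood is not a peak); plateau ties
  # are then resolved by ascending (z,y,x) scan order.
  is_max <- sm >= neigh & sm > neigh_min & raw > intensity_floor
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) > 1) {
    # order candidates by (z, y, x); drop any candidate whose neighbourhood
    # contains an earlier candidate of equal smoothed value
    ord <- order(idx[, 1], idx[, 2], idx[, 3])
    idx <- idx[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(idx))
    for (i in seq_len(nrow(idx))[-1]) {
      for (j in seq_len(i - 1)) {
        if (!keep[j]) next
        if (all(abs(idx[i, ] - idx[j, ]) <= 1) &&
            sm[idx[i, 1], idx[i, 2], idx[i, 3]] ==
            sm[idx[j, 1], idx[j, 2], idx[j, 3]]) {
          keep[i] <- FALSE
          break
        }
      }
    }
    idx <- idx[keep, , drop = FALSE]
  }
  if (nrow(idx) == 0)
    return(data.frame(z = integer(0), y = integer(0), x = integer(0),
                      peak_intensity = numeric(0), isolation_ok = logical(0)))
  colnames(idx) <- c("z", "y", "x")
  # merge duplicate maxima of a single bead: keep the brightest candidate
  # within merge_radius (ties by scan order, which the ordering preserves)
  if (nrow(idx) > 1 && merge_radius > 0) {
    pz <- (idx[, "z"] - 1) * stack$axial_step
    py <- (idx[, "y"] - 1) * stack$lateral_step
    px <- (idx[, "x"] - 1) * stack$lateral_step
    ord <- order(-raw[idx], idx[, 1], idx[, 2], idx[, 3])
    keep <- logical(nrow(idx))
    for (i in ord) {
      kept <- which(keep)
      if (!length(kept) ||
          all((pz[kept] - pz[i])^2 + (py[kept] - py[i])^2 +
              (px[kept] - px[i])^2 >= merge_radius^2))
        keep[i] <- TRUE
    }
    idx <- idx[keep, , drop = FALSE]
  }
  pz <- (idx[, "z"] - 1) * stack$axial_step
  py <- (idx[, "y"] - 1) * stack$lateral_step
  px <- (idx[, "x"] - 1) * stack$lateral_step
  d <- dim(raw)
  zmax <- (d[1] - 1) * stack$axial_step
  ymax <- (d[2] - 1) * stack$lateral_step
  xmax <- (d[3] - 1) * stack$lateral_step
  near_border <- pz < border_margin | (zmax - pz) < border_margin |
    py < border_margin | (ymax - py) < border_margin |
    px < border_margin | (xmax - px) < border_margin
  n <- nrow(idx)
  crowded <- rep(FALSE, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      d2 <- (pz - pz[i])^2 + (py - py[i])^2 + (px - px[i])^2
      d2[i] <- Inf
      crowded[i] <- min(d2) < min_separation^2
    }
  }
  data.frame(z = idx[, "z"], y = idx[, "y"], x = idx[, "x"],
             peak_intensity = raw[idx],
             isolation_ok = !near_border & !crowded)
}

#' Extract a 1D intensity profile through a peak voxel
#'
#' A single-voxel-wide line through the peak along the chosen axis, with
#' positions in um centred at 0 at the peak voxel. Default half-windows are
#' 1.5 um laterally and 4 um axially.
#'
#' @param stack An [image_stack()].
#' @param peak_voxel Integer `(z, y, x)` voxel indices (1-based).
#' @param axis `"lateral_x"` or `"axial_z"`.
#' @param half_width Half-window in um; `NULL` uses the axis default.
#' @return A data.frame of class `intensity_profile` with columns
#'   `position` (um) and `value`, plus attributes `axis` and `step`.
#' @export
extract_profile <- function(stack, peak_voxel,
                            axis = c("lateral_x", "axial_z"),
                            half_width = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  axis <- match.arg(axis)
  peak_voxel <- as.integer(peak_voxel)
  d <- dim(stack$voxels)
  if (length(peak_voxel) != 3 || any(peak_voxel < 1) ||
      any(peak_voxel > d))
    stop("peak_voxel must be valid (z, y, x) indices", call. = FALSE)
  step <- if (axis == "axial_z") stack$axial_step else stack$lateral_step
  if (is.null(half_width))
    half_width <- if (axis == "axial_z") 4.0 else 1.5
  hw <- floor(half_width / step + 1e-9)
  centre <- if (axis == "axial_z") peak_voxel[1] else peak_voxel[3]
  n_axis <- if (axis == "axial_z") d[1] else d[3]
  lo <- centre - hw; hi <- centre + hw
  if (lo < 1 || hi > n_axis)
    stop("profile window (+/-", half_width, " um) exceeds the stack along ",
         axis, call. = FALSE)
  values <- if (axis == "axial_z")
    stack$voxels[lo:hi, peak_voxel[2], peak_voxel[3]]
  else
    stack$voxels[peak_voxel[1], peak_voxel[2], lo:hi]
  out <- data.frame(position = (seq(lo, hi) - centre) * step, value = values)
  attr(out, "axis") <- axis
  attr(out, "step") <- step
  class(out) <- c("intensity_profile", "data.frame")
  out
}

#' Measure a profile FWHM by half-maximum crossings
#'
#' Model-free width estimate: the distance between the two crossings of
#' half of (max - baseline), located by linear interpolation between
#' samples. Used as the independent oracle for the Gaussian fit.
#'
#' @param profile An `intensity_profile` (or data.frame with `position`,
#'   `value`).
#' @param baseline Baseline level subtracted before halving; defaults to
#'   the profile minimum.
#' @return FWHM in um (NA when the profile does not cross half maximum on
#'   both sides).
#' @export
half_max_width <- function(profile, baseline = min(profile$value)) {
  u <- profile$position
  v <- profile$value - baseline
  imax <- which.max(v)
  half <- v[imax] / 2
  left <- NA_real_
  for (i in seq(imax, 2)) {
    if (v[i - 1] <= half && v[i] >= half) {
      left <- u[i - 1] + (half - v[i - 1]) / (v[i] - v[i - 1]) *
        (u[i] - u[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in seq(imax, length(v) - 1)) {
    if (v[i + 1] <= half && v[i] >= half) {
      right <- u[i] + (v[i] - half) / (v[i] - v[i + 1]) * (u[i + 1] - u[i])
      break
    }
  }
  right - left
}

#' Fit a Gaussian to an intensity profile
#'
#' Least-squares fit of `A * exp(-(u - mu)^2 / (2 sigma^2)) + b` with
#' starting values from sample moments. In `fixed_center` mode the centre
#' is pinned at 0 um (the peak voxel), the presumption used for blurry
#' motion-affected beads; `free_center` estimates it. The FWHM is
#' `2 sqrt(2 ln 2) sigma`. Fits with root-mean-square residual above 20%
#' of the fitted amplitude are flagged unreliable.
#'
#' @param profile An `intensity_profile` with at least 7 samples whose
#'   maximum is not at either edge.
#' @param mode `"free_center"` or `"fixed_center"`.
#' @return An object of class `fwhm_fit` with elements `fwhm`, `amplitude`,
#'   `center`, `sigma`, `offset`, `fit_rmse`, `mode`, `reliable`.
#' @examples
#' u <- seq(-3, 3, by = 0.25)
#' prof <- data.frame(position = u, value = 10 * exp(-u^2 / 2) + 1)
#' fit_gaussian(prof)$fwhm  # 2.3548 (sigma = 1)
#' @export
fit_gaussian <- function(profile, mode = c("free_center", "fixed_center")) {
  mode <- match.arg(mode)
  u <- profile$position
  v <- profile$value
  if (length(u) < 7)
    stop("profile must contain at least 7 samples", call. = FALSE)
  imax <- which.max(v)
  if (imax == 1 || imax == length(v))
    stop("profile peak lies at the window edge; enlarge the window",
         call. = FALSE)
  b0 <- min(v)
  A0 <- max(v) - b0
  w <- pmax(v - b0, 0)
  mu0 <- if (mode == "fixed_center") 0 else sum(u * w) / sum(w)
  s0 <- sqrt(sum((u - mu0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(u)) / 6
  if (mode == "free_center") {
    start <- c(A = A0, mu = mu0, s = s0, b = b0)
    lower <- c(A = 0, mu = min(u), s = 1e-6, b = -Inf)
    upper <- c(A = Inf, mu = max(u), s = diff(range(u)), b = Inf)
    model <- function(p) p["A"] * exp(-(u - p["mu"])^2 / (2 * p["s"]^2)) +
      p["b"]
  } else {
    start <- c(A = A0, s = s0, b = b0)
    lower <- c(A = 0, s = 1e-6, b = -Inf)
    upper <- c(A = Inf, s = diff(range(u)), b = Inf)
    model <- function(p) p["A"] * exp(-u^2 / (2 * p["s"]^2)) + p["b"]
  }
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = function(p) model(p) - v,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  if (!fit$info %in% 1:4)
    stop("Gaussian fit failed to converge (", fit$message, "); n = ",
         length(u), ", mode = ", mode, call. = FALSE)
  est <- fit$par
  if (!("mu" %in% names(est))) est[["mu"]] <- 0
  rmse <- sqrt(fit$deviance / length(u))
  out <- list(fwhm = FWHM_SIGMA * est[["s"]],
              amplitude = est[["A"]],
              center = if (mode == "free_center") est[["mu"]] else 0,
              sigma = est[["s"]],
              offset = est[["b"]],
              fit_rmse = rmse,
              mode = mode,
              reliable = rmse <= 0.2 * est[["A"]],
              n = length(u))
  class(out) <- "fwhm_fit"
  out
}

#' @export
print.fwhm_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian fit (%s): FWHM = %.4f um (sigma %.4f), A = %.3g, b = %.3g, rmse = %.3g%s\n",
    x$mode, x$fwhm, x$sigma, x$amplitude, x$offset, x$fit_rmse,
    if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}

#' @export
coef.fwhm_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center = object$center,
    sigma = object$sigma, offset = object$offset)
}

#' Measure lateral and axial FWHMs of one detected bead
#'
#' Lateral width from the x-profile, axial width from the z-profile, both
#' via [fit_gaussian()] in the requested mode. The bead is flagged
#' `reliable` only when both fits are.
#'
#' @param stack An [image_stack()].
#' @param detection One row of the [detect_beads()] output (or any list
#'   with `z`, `y`, `x`), which must be isolation-approved by the caller.
#' @param mode Fit mode, see [fit_gaussian()].
#' @return A one-row data.frame: `fwhm_xy`, `fwhm_z`, `reliable`, `mode`.
#' @export
measure_bead <- function(stack, detection,
                         mode = c("free_center", "fixed_center")) {
  mode <- match.arg(mode)
  pv <- c(detection$z, detection$y, detection$x)
  fx <- fit_gaussian(extract_profile(stack, pv, "lateral_x"), mode)
  fz <- fit_gaussian(extract_profile(stack, pv, "axial_z"), mode)
  data.frame(fwhm_xy = fx$fwhm, fwhm_z = fz$fwhm,
             reliable = fx$reliable && fz$reliable, mode = mode)
}

#' Summarise bead measurements for one imaging condition
#'
#' Arithmetic mean and standard error of the mean (sd / sqrt(n)) of the
#' reliable measurements, per axis. With a single measurement the s.e.m.
#' is reported as NA (undefined), not 0.
#'
#' @param measurements A data.frame with `fwhm_xy`, `fwhm_z` and optionally
#'   `reliable` (rows with `reliable = FALSE` are dropped).
#' @param condition The [imaging_condition()] the beads were imaged under.
#' @return An object of class `condition_summary`.
#' @export
summarize_condition <- function(measurements, condition = NULL) {
  if (!is.null(measurements$reliable))
    measurements <- measurements[measurements$reliable, , drop = FALSE]
  n <- nrow(measurements)
  if (is.null(n) || n < 1)
    stop("no reliable measurements to summarise", call. = FALSE)
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  out <- list(mean_fwhm_xy = mean(measurements$fwhm_xy),
              sem_fwhm_xy = sem(measurements$fwhm_xy),
              mean_fwhm_z = mean(measurements$fwhm_z),
              sem_fwhm_z = sem(measurements$fwhm_z),
              n_beads = n, condition = condition)
  class(out) <- "condition_summary"
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf(
    "FWHM_xy = %.2f +/- %.2f um, FWHM_z = %.2f +/- %.2f um (n = %d beads)\n",
    x$mean_fwhm_xy, x$sem_fwhm_xy, x$mean_fwhm_z, x$sem_fwhm_z, x$n_beads))
  if (!is.null(x$condition)) print(x$condition)
  invisible(x)
}

#' Focal-volume expansion ratio between two conditions
#'
#' Element-wise ratio of mean FWHMs, deep over shallow, reported both at
#' two decimals and at the conventional one-decimal rounding.
#'
#' @param summary_deep,summary_shallow [summarize_condition()] outputs.
#' @return A list with `lateral`, `axial` (2 dp) and `lateral_1dp`,
#'   `axial_1dp`.
#' @examples
#' deep <- summarize_condition(data.frame(fwhm_xy = 0.53, fwhm_z = 4.14))
#' shallow <- summarize_condition(data.frame(fwhm_xy = 0.41, fwhm_z = 2.16))
#' expansion_ratio(deep, shallow)  # lateral 1.29 -> 1.3, axial 1.92 -> 1.9
#' @export
expansion_ratio <- function(summary_deep, summary_shallow) {
  stopifnot(inherits(summary_deep, "condition_summary"),
            inherits(summary_shallow, "condition_summary"))
  if (summary_shallow$mean_fwhm_xy == 0 || summary_shallow$mean_fwhm_z == 0)
    stop("shallow summary has zero mean FWHM", call. = FALSE)
  lat <- summary_deep$mean_fwhm_xy / summary_shallow$mean_fwhm_xy
  axi <- summary_deep$mean_fwhm_z / summary_shallow$mean_fwhm_z
  list(lateral = round(lat, 2), axial = round(axi, 2),
       lateral_1dp = round(lat, 1), axial_1dp = round(axi, 1))
}
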