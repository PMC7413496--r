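# Synthetic-data generators: bead stacks, neurite-like structure stacks and
# calcium movies with known ground truth. These emulate the statistical
# structure the analysis stages assume (anisotropic Gaussian focal volumes
# that widen with depth and RI mismatch, shot + read noise, frame-to-frame
# jitter, dark-vessel backgrounds) so the whole pipeline is testable without
# microscope data.

# Evaluate code with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Bead-field simulation parameters
#'
#' Defaults follow the bead-imaging protocol the analysis targets: 0.05
#' um/pixel lateral and 0.25 um/plane axial sampling, 200-nm beads, and a
#' small rigid per-plane jitter standing in for heartbeat/breathing motion.
#'
#' @param stack_shape Integer vector `(z, y, x)` in voxels.
#' @param lateral_step,axial_step Sampling in um.
#' @param n_beads Number of beads to place.
#' @param bead_diameter Bead diameter in um (0.2 or 1.0 presets).
#' @param min_separation Minimum pairwise centre distance, um; must exceed
#'   `bead_diameter`.
#' @param peak_photons Expected photon count at a bead peak.
#' @param read_noise_sd Additive Gaussian detector noise SD, counts.
#' @param jitter_sd Per-plane lateral displacement SD, um (0 disables).
#' @param fwhm_cv Bead-to-bead coefficient of variation of the effective
#'   widths (0 disables). Real bead ensembles show ~10% relative spread in
#'   measured widths; the default reproduces that dispersion.
#' @param poisson Apply Poisson (shot) noise to expected photons.
#' @param margin_lateral,margin_axial Keep-out distance of bead centres from
#'   the stack faces, um (large enough for the profile windows used by the
#'   metrology stage).
#' @param seed Integer seed; a fixed seed makes the output bit-reproducible.
#' @return A list of class `bead_field_params`.
#' @export
bead_field_params <- function(stack_shape = c(48, 80, 80),
                              lateral_step = 0.05, axial_step = 0.25,
                              n_beads = 1, bead_diameter = 0.2,
                              min_separation = 2, peak_photons = 1000,
                              read_noise_sd = 2, jitter_sd = 0.05,
                              fwhm_cv = 0.10, poisson = TRUE,
                              margin_lateral = 1.75, margin_axial = 4.5,
                              seed = NULL) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1),
            lateral_step > 0, axial_step > 0, n_beads >= 0,
            bead_diameter > 0, peak_photons > 0, read_noise_sd >= 0,
            jitter_sd >= 0, fwhm_cv >= 0)
  if (min_separation <= bead_diameter)
    stop("min_separation must exceed bead_diameter", call. = FALSE)
  structure(list(stack_shape = as.integer(stack_shape),
                 lateral_step = lateral_step, axial_step = axial_step,
                 n_beads = as.integer(n_beads),
                 bead_diameter = bead_diameter,
                 min_separation = min_separation,
                 peak_photons = peak_photons, read_noise_sd = read_noise_sd,
                 jitter_sd = jitter_sd, fwhm_cv = fwhm_cv, poisson = poisson,
                 margin_lateral = margin_lateral, margin_axial = margin_axial,
                 seed = seed),
            class = "bead_field_params")
}

# Effective per-axis Gaussian sigmas for a bead of given diameter imaged
# with an effective focal volume `psf`. The preset FWHMs are the *measured*
# widths obtained with 200-nm beads, so only the excess second moment of
# larger beads is added: var_eff = var_psf + (d^2 - 0.2^2)/20 for d > 0.2 um
# (a uniform ball of diameter d has per-axis variance d^2/20).
effective_sigmas <- function(psf, bead_diameter) {
  extra <- if (bead_diameter > 0.2) (bead_diameter^2 - 0.2^2) / 20 else 0
  c(lateral = sqrt((unname(psf$fwhm_lateral) / FWHM_SIGMA)^2 + extra),
    axial   = sqrt((unname(psf$fwhm_axial)   / FWHM_SIGMA)^2 + extra))
}

place_beads <- function(params) {
  d <- params$stack_shape
  zmax <- (d[1] - 1) * params$axial_step
  ymax <- (d[2] - 1) * params$lateral_step
  xmax <- (d[3] - 1) * params$lateral_step
  lo <- c(params$margin_axial, params$margin_lateral, params$margin_lateral)
  hi <- c(zmax - params$margin_axial, ymax - params$margin_lateral,
          xmax - params$margin_lateral)
  if (params$n_beads > 0 && any(hi < lo))
    stop("stack too small to hold beads inside the border margins",
         call. = FALSE)
  centers <- matrix(numeric(0), ncol = 3,
                    dimnames = list(NULL, c("z", "y", "x")))
  retries <- 10L * max(1L, params$n_beads)
  attempts <- 0L
  while (nrow(centers) < params$n_beads) {
    if (attempts >= retries + params$n_beads)
      stop("could not place ", params$n_beads, " beads at min_separation ",
           params$min_separation, " um after ", attempts, " attempts",
           call. = FALSE)
    attempts <- attempts + 1L
    cand <- lo + stats::runif(3) * (hi - lo)
    ok <- TRUE
    if (nrow(centers) > 0) {
      dist2 <- (centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2 +
        (centers[, 3] - cand[3])^2
      ok <- all(dist2 >= params$min_separation^2)
    }
    if (ok) centers <- rbind(centers, cand)
  }
  centers
}

#' Simulate a 3D bead stack with known ground truth
#'
#' Beads are rendered as effective anisotropic Gaussians whose widths equal
#' the requested focal-volume widths (see [psf_spec()]); beads larger than
#' 200 nm additionally carry their excess second moment, so 1.0-um beads
#' render wider than the nominal widths. Optional rigid per-plane lateral
#' jitter emulates heartbeat/breathing motion; Poisson shot noise and
#' Gaussian read noise are applied to the expected photon counts.
#'
#' @param params A [bead_field_params()].
#' @param psf A [psf_spec()] giving the effective focal-volume widths.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (bead centres in um, the requested widths, the per-plane jitter).
#' @examples
#' p <- bead_field_params(n_beads = 1, poisson = FALSE, read_noise_sd = 0,
#'                        jitter_sd = 0, fwhm_cv = 0, seed = 1)
#' sim <- generate_bead_stack(p, psf_spec(0.41, 2.16))
#' dim(sim$stack)
#' @export
generate_bead_stack <- function(params, psf) {
  stopifnot(inherits(params, "bead_field_params"), inherits(psf, "psf_spec"))
  with_seed(params$seed, {
    d <- params$stack_shape
    centers <- place_beads(params)
    nb <- nrow(centers)
    # per-bead effective widths: multiplicative dispersion around the
    # requested values (independent lateral/axial factors, floored at 0.2)
    factors <- if (params$fwhm_cv > 0 && nb > 0)
      matrix(pmax(0.2, 1 + stats::rnorm(2 * nb, 0, params$fwhm_cv)),
             ncol = 2, dimnames = list(NULL, c("lateral", "axial")))
    else matrix(1, nrow = nb, ncol = 2,
                dimnames = list(NULL, c("lateral", "axial")))
    zpos <- (seq_len(d[1]) - 1) * params$axial_step
    ypos <- (seq_len(d[2]) - 1) * params$lateral_step
    xpos <- (seq_len(d[3]) - 1) * params$lateral_step
    jitter <- if (params$jitter_sd > 0)
      matrix(stats::rnorm(2 * d[1], 0, params$jitter_sd), ncol = 2,
             dimnames = list(NULL, c("dy", "dx")))
    else matrix(0, nrow = d[1], ncol = 2,
                dimnames = list(NULL, c("dy", "dx")))
    expected <- array(0, dim = d)
    bead_fwhm <- cbind(lateral = psf$fwhm_lateral * factors[, "lateral"],
                       axial = psf$fwhm_axial * factors[, "axial"])
    for (b in seq_len(nrow(centers))) {
      sig <- effective_sigmas(list(fwhm_lateral = bead_fwhm[b, "lateral"],
                                   fwhm_axial = bead_fwhm[b, "axial"]),
                              params$bead_diameter)
      cz <- centers[b, 1]; cy <- centers[b, 2]; cx <- centers[b, 3]
      kz <- which(abs(zpos - cz) <= 5 * sig["axial"])
      for (k in kz) {
        az <- exp(-(zpos[k] - cz)^2 / (2 * sig["axial"]^2))
        jy <- cy + jitter[k, 1]; jx <- cx + jitter[k, 2]
        iy <- which(abs(ypos - jy) <= 5 * sig["lateral"])
        ix <- which(abs(xpos - jx) <= 5 * sig["lateral"])
        if (!length(iy) || !length(ix)) next
        gy <- exp(-(ypos[iy] - jy)^2 / (2 * sig["lateral"]^2))
        gx <- exp(-(xpos[ix] - jx)^2 / (2 * sig["lateral"]^2))
        expected[k, iy, ix] <- expected[k, iy, ix] +
          params$peak_photons * az * outer(gy, gx)
      }
    }
    voxels <- expected
    if (params$poisson)
      voxels <- array(stats::rpois(length(expected), expected), dim = d)
    if (params$read_noise_sd > 0)
      voxels <- voxels + array(stats::rnorm(length(voxels), 0,
                                            params$read_noise_sd), dim = d)
    voxels[voxels < 0] <- 0
    list(stack = image_stack(voxels, params$lateral_step, params$axial_step),
         truth = list(centers = centers, true_fwhm = psf,
                      bead_fwhm = bead_fwhm,
                      bead_diameter = params$bead_diameter, jitter = jitter))
  })
}

# Dense separable Gaussian blur along each array axis (zero-padded
# boundaries); kernel truncated at 4 sigma.
conv_matrix <- function(n, sigma_px) {
  if (sigma_px <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_px))
  g <- exp(-(-half:half)^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (o in -half:half) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- g[o + half + 1]
  }
  # renormalise truncated boundary columns so constants are preserved
  sweep(K, 2, colSums(K), "/")
}

gauss_blur_3d <- function(arr, sigma_z_px, sigma_y_px, sigma_x_px) {
  d <- dim(arr)
  # x axis
  m <- matrix(arr, d[1] * d[2], d[3])
  arr <- array(m %*% conv_matrix(d[3], sigma_x_px), dim = d)
  # y axis
  p <- aperm(arr, c(1, 3, 2))
  m <- matrix(p, d[1] * d[3], d[2])
  p <- array(m %*% conv_matrix(d[2], sigma_y_px), dim = c(d[1], d[3], d[2]))
  arr <- aperm(p, c(1, 3, 2))
  # z axis
  p <- aperm(arr, c(2, 3, 1))
  m <- matrix(p, d[2] * d[3], d[1])
  p <- array(m %*% conv_matrix(d[1], sigma_z_px), dim = c(d[2], d[3], d[1]))
  aperm(p, c(3, 1, 2))
}

#' Structure-field simulation parameters
#'
#' @param stack_shape Integer `(z, y, x)` voxel shape.
#' @param lateral_step,axial_step Sampling, um.
#' @param n_filaments Number of dendrite-like filaments (~1 um diameter).
#' @param filament_diameter,spine_diameter Structure diameters, um.
#' @param n_spines Spine-like protrusions per filament.
#' @param amplitude Peak expected photon count of a filament core.
#' @param background Expected background photon count per voxel.
#' @param read_noise_sd Gaussian read noise SD, counts.
#' @param poisson Apply shot noise.
#' @param seed Integer seed.
#' @return A list of class `structure_field_params`.
#' @export
structure_field_params <- function(stack_shape = c(21, 96, 96),
                                   lateral_step = 0.1, axial_step = 0.5,
                                   n_filaments = 6,
                                   filament_diameter = 1.0,
                                   spine_diameter = 0.5, n_spines = 3,
                                   amplitude = 100, background = 5,
                                   read_noise_sd = 2, poisson = TRUE,
                                   seed = NULL) {
  stopifnot(length(stack_shape) == 3, all(stack_shape >= 1),
            lateral_step > 0, axial_step > 0, n_filaments >= 0,
            filament_diameter > 0, spine_diameter > 0, amplitude > 0,
            background >= 0)
  structure(list(stack_shape = as.integer(stack_shape),
                 lateral_step = lateral_step, axial_step = axial_step,
                 n_filaments = as.integer(n_filaments),
                 filament_diameter = filament_diameter,
                 spine_diameter = spine_diameter,
                 n_spines = as.integer(n_spines),
                 amplitude = amplitude, background = background,
                 read_noise_sd = read_noise_sd, poisson = poisson,
                 seed = seed),
            class = "structure_field_params")
}

# Add a Gaussian blob of peak `amp` and isotropic physical sigma at a
# physical position (um) into `arr` (in place via return).
add_blob <- function(arr, pos, sigma, amp, steps) {
  d <- dim(arr)
  zpos <- (seq_len(d[1]) - 1) * steps[1]
  ypos <- (seq_len(d[2]) - 1) * steps[2]
  xpos <- (seq_len(d[3]) - 1) * steps[3]
  kz <- which(abs(zpos - pos[1]) <= 3 * sigma)
  iy <- which(abs(ypos - pos[2]) <= 3 * sigma)
  ix <- which(abs(xpos - pos[3]) <= 3 * sigma)
  if (!length(kz) || !length(iy) || !length(ix)) return(arr)
  gz <- exp(-(zpos[kz] - pos[1])^2 / (2 * sigma^2))
  gy <- exp(-(ypos[iy] - pos[2])^2 / (2 * sigma^2))
  gx <- exp(-(xpos[ix] - pos[3])^2 / (2 * sigma^2))
  blob <- amp * outer(gz, outer(gy, gx))
  arr[kz, iy, ix] <- pmax(arr[kz, iy, ix], blob)
  arr
}

#' Simulate a neurite-like structure stack
#'
#' Renders randomly oriented bright filaments (~1 um diameter, roughly
#' in-plane like dendrites) with thinner spine-like protrusions, blurs the
#' scene with the supplied focal-volume widths, and adds background, shot
#' and read noise. The blur-free reference is returned alongside, so
#' contrast metrics can be compared against an aberration-free bound.
#'
#' @param params A [structure_field_params()].
#' @param psf A [psf_spec()] used for the blur.
#' @return A list with `stack` (noisy, blurred), `reference` (blur- and
#'   noise-free expected scene) — both [image_stack()] objects.
#' @export
generate_structure_stack <- function(params, psf) {
  stopifnot(inherits(params, "structure_field_params"),
            inherits(psf, "psf_spec"))
  with_seed(params$seed, {
    d <- params$stack_shape
    steps <- c(params$axial_step, params$lateral_step, params$lateral_step)
    extent <- (d - 1) * steps
    ref <- array(0, dim = d)
    fil_sigma <- params$filament_diameter / FWHM_SIGMA
    spi_sigma <- params$spine_diameter / FWHM_SIGMA
    for (f in seq_len(params$n_filaments)) {
      p0 <- stats::runif(3) * extent
      dir <- c(0.3 * stats::rnorm(1), stats::rnorm(2))  # mostly in-plane
      dir <- dir / sqrt(sum(dir^2))
      len <- max(extent)  # span the field
      ts <- seq(-len, len, by = fil_sigma / 2)
      spine_ts <- sample(ts, min(params$n_spines, length(ts)))
      for (t in ts) {
        pos <- p0 + t * dir
        if (any(pos < -3 * fil_sigma) || any(pos > extent + 3 * fil_sigma))
          next
        ref <- add_blob(ref, pos, fil_sigma, params$amplitude, steps)
      }
      perp <- c(0, -dir[3], dir[2])
      if (sum(perp^2) < 1e-9) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      for (t0 in spine_ts) {
        base <- p0 + t0 * dir
        for (s in seq(0, 1.2, by = spi_sigma / 2)) {
          pos <- base + s * perp
          if (any(pos < 0) || any(pos > extent)) next
          ref <- add_blob(ref, pos, spi_sigma, 0.8 * params$amplitude, steps)
        }
      }
    }
    blurred <- gauss_blur_3d(ref,
                             (psf$fwhm_axial / FWHM_SIGMA) / params$axial_step,
                             (psf$fwhm_lateral / FWHM_SIGMA) / params$lateral_step,
                             (psf$fwhm_lateral / FWHM_SIGMA) / params$lateral_step)
    expected <- blurred + params$background
    voxels <- expected
    if (params$poisson)
      voxels <- array(stats::rpois(length(expected), expected), dim = d)
    if (params$read_noise_sd > 0)
      voxels <- voxels + array(stats::rnorm(length(voxels), 0,
                                            params$read_noise_sd), dim = d)
    voxels[voxels < 0] <- 0
    list(stack = image_stack(voxels, params$lateral_step, params$axial_step),
         reference = image_stack(ref, params$lateral_step, params$axial_step))
  })
}

#' Calcium-movie simulation parameters
#'
#' Emulates spontaneous astrocyte calcium transients over a dark blood
#' vessel: static cell regions with baseline fluorescence, transient events
#' (exponential rise and decay) confined to contiguous subregions of at
#' least 21 pixels, sub-threshold distractor events of at most 20 pixels,
#' and a vessel band carrying no cell signal.
#'
#' @param frame_shape Integer `(y, x)` pixel shape.
#' @param n_frames Number of frames.
#' @param frame_interval Seconds per frame.
#' @param n_cells Number of cell regions.
#' @param event_rate Events per cell per 100 frames.
#' @param n_events Optional exact number of events per cell, overriding the
#'   Poisson draw from `event_rate` (useful for controlled fixtures).
#' @param event_amplitude Peak event amplitude as a fraction of baseline F.
#' @param event_area Range (min, max) of true-event areas, pixels (>= 21).
#' @param n_distractors Number of sub-threshold (<= 20 px) distractor events.
#' @param distractor_area Range of distractor areas, pixels (<= 20).
#' @param vessel_fraction Fraction of the frame width taken by the vessel.
#' @param baseline_f Cell baseline fluorescence, counts.
#' @param neuropil_fraction Out-of-cell baseline as a fraction of
#'   `baseline_f`.
#' @param background_offset Additive detector offset, counts.
#' @param noise_sd Gaussian noise SD, counts (0 disables).
#' @param poisson Apply shot noise to expected counts.
#' @param seed Integer seed.
#' @return A list of class `calcium_movie_params`.
#' @export
calcium_movie_params <- function(frame_shape = c(64, 64), n_frames = 40,
                                 frame_interval = 1, n_cells = 4,
                                 event_rate = 5, n_events = NULL,
                                 event_amplitude = 1,
                                 event_area = c(25, 60),
                                 n_distractors = 2,
                                 distractor_area = c(8, 20),
                                 vessel_fraction = 0.12, baseline_f = 600,
                                 neuropil_fraction = 0.3,
                                 background_offset = 2, noise_sd = 1,
                                 poisson = TRUE, seed = NULL) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 8), n_frames >= 2,
            frame_interval > 0, n_cells >= 0, event_rate >= 0,
            event_amplitude >= 0, vessel_fraction >= 0, vessel_fraction < 1,
            baseline_f >= 0, noise_sd >= 0)
  stopifnot(event_area[1] >= 21, distractor_area[2] <= 20)
  structure(list(frame_shape = as.integer(frame_shape),
                 n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 n_cells = as.integer(n_cells), event_rate = event_rate,
                 n_events = if (!is.null(n_events)) as.integer(n_events),
                 event_amplitude = event_amplitude,
                 event_area = event_area,
                 n_distractors = as.integer(n_distractors),
                 distractor_area = distractor_area,
                 vessel_fraction = vessel_fraction,
                 baseline_f = baseline_f,
                 neuropil_fraction = neuropil_fraction,
                 background_offset = background_offset,
                 noise_sd = noise_sd, poisson = poisson, seed = seed),
            class = "calcium_movie_params")
}

# Grow a contiguous pixel region of `target` pixels inside `allowed`
# (logical matrix) from a random allowed seed pixel, 4-neighbour growth.
grow_region <- function(allowed, target) {
  idx <- which(allowed)
  if (!length(idx)) return(integer(0))
  ny <- nrow(allowed)
  start <- idx[sample.int(length(idx), 1)]
  region <- integer(0)
  frontier <- start
  inreg <- matrix(FALSE, nrow(allowed), ncol(allowed))
  while (length(region) < target && length(frontier)) {
    cur <- frontier[1]
    frontier <- frontier[-1]
    if (inreg[cur]) next
    inreg[cur] <- TRUE
    region <- c(region, cur)
    y <- (cur - 1) %% ny + 1
    x <- (cur - 1) %/% ny + 1
    nb <- c(if (y > 1) cur - 1, if (y < ny) cur + 1,
            if (x > 1) cur - ny, if (x < ncol(allowed)) cur + ny)
    nb <- nb[allowed[nb] & !inreg[nb]]
    frontier <- c(frontier, nb[sample.int(length(nb))])
  }
  region
}

event_kernel <- function(n_frames, onset, tau_rise = 1, tau_decay = 5) {
  t <- seq_len(n_frames) - onset
  k <- ifelse(t < 0, 0, (1 - exp(-(t + 1) / tau_rise)) * exp(-t / tau_decay))
  m <- max(k)
  if (m > 0) k / m else k
}

#' Simulate a calcium-imaging movie with known event ground truth
#'
#' See [calcium_movie_params()] for the scene model. Events with areas of at
#' least 21 pixels are "true" events that the downstream >20-pixel area
#' filter must keep; distractors of at most 20 pixels must be rejected.
#'
#' @param params A [calcium_movie_params()].
#' @return A list with `movie` (a [ca_movie()]), `vessel_mask` (logical
#'   y-by-x matrix), and `truth` (a data.frame of events with their pixel
#'   sets as a list column `pixels`, linear column-major indices).
#' @export
generate_calcium_movie <- function(params) {
  stopifnot(inherits(params, "calcium_movie_params"))
  with_seed(params$seed, {
    ny <- params$frame_shape[1]; nx <- params$frame_shape[2]
    nt <- params$n_frames
    # vessel: a wiggly vertical band
    vw <- max(1L, round(params$vessel_fraction * nx))
    x0 <- round(nx * 0.15)
    vessel <- matrix(FALSE, ny, nx)
    if (params$vessel_fraction > 0) {
      wig <- round(2 * sin(seq_len(ny) / ny * 2 * pi))
      for (y in seq_len(ny)) {
        cols <- pmin(nx, pmax(1, (x0 + wig[y]):(x0 + wig[y] + vw - 1)))
        vessel[y, cols] <- TRUE
      }
    }
    # cells: discs placed outside the vessel and away from borders
    cells <- vector("list", params$n_cells)
    cell_map <- matrix(0L, ny, nx)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    placed <- 0L; tries <- 0L
    while (placed < params$n_cells && tries < 50L * max(1L, params$n_cells)) {
      tries <- tries + 1L
      r <- stats::runif(1, 4, 6)
      cy <- stats::runif(1, r + 2, ny - r - 1)
      cx <- stats::runif(1, r + 2, nx - r - 1)
      disc <- (yy - cy)^2 + (xx - cx)^2 <= r^2
      if (any(disc & vessel) || any(disc & cell_map > 0)) next
      placed <- placed + 1L
      cell_map[disc] <- placed
      cells[[placed]] <- which(disc)
    }
    if (placed < params$n_cells)
      stop("could not place ", params$n_cells, " cells; reduce n_cells or ",
           "vessel_fraction", call. = FALSE)
    baseline <- matrix(params$neuropil_fraction * params$baseline_f, ny, nx)
    baseline[cell_map > 0] <- params$baseline_f
    baseline[vessel] <- 0
    # events
    events <- list()
    add_event <- function(cell_id, area, is_distractor) {
      allowed <- matrix(FALSE, ny, nx)
      allowed[cells[[cell_id]]] <- TRUE
      px <- grow_region(allowed, area)
      if (length(px) < area) return(NULL)
      onsets <- seq(2L, max(2L, nt - 8L))
      onset <- onsets[sample.int(length(onsets), 1)]
      list(cell = cell_id, onset = onset, area = length(px),
           amplitude = params$event_amplitude * params$baseline_f,
           is_distractor = is_distractor, pixels = px)
    }
    if (params$n_cells > 0) {
      for (cell_id in seq_len(params$n_cells)) {
        n_ev <- if (!is.null(params$n_events)) params$n_events
        else stats::rpois(1, params$event_rate * nt / 100)
        for (e in seq_len(n_ev)) {
          amax <- min(params$event_area[2], length(cells[[cell_id]]))
          areas <- seq(params$event_area[1], max(params$event_area[1], amax))
          area <- areas[sample.int(length(areas), 1)]
          ev <- add_event(cell_id, area, FALSE)
          if (!is.null(ev)) events[[length(events) + 1L]] <- ev
        }
      }
      for (dd in seq_len(params$n_distractors)) {
        cell_id <- sample.int(params$n_cells, 1)
        areas <- seq(params$distractor_area[1], params$distractor_area[2])
        area <- areas[sample.int(length(areas), 1)]
        ev <- add_event(cell_id, area, TRUE)
        if (!is.null(ev)) events[[length(events) + 1L]] <- ev
      }
    }
    expected <- aperm(array(baseline, dim = c(ny, nx, nt)), c(3, 1, 2))
    for (ev in events) {
      k <- event_kernel(nt, ev$onset)
      act <- which(k > 1e-3)
      for (t in act) {
        frame <- matrix(0, ny, nx)
        frame[ev$pixels] <- ev$amplitude * k[t]
        expected[t, , ] <- expected[t, , ] + frame
      }
    }
    expected <- expected + params$background_offset
    frames <- expected
    if (params$poisson)
      frames <- array(stats::rpois(length(expected), expected),
                      dim = dim(expected))
    if (params$noise_sd > 0)
      frames <- frames + array(stats::rnorm(length(frames), 0,
                                            params$noise_sd),
                               dim = dim(frames))
    frames[frames < 0] <- 0
    truth <- if (length(events)) {
      df <- data.frame(cell = vapply(events, `[[`, 0L, "cell"),
                       onset = vapply(events, `[[`, 0L, "onset"),
                       area = vapply(events, function(e) length(e$pixels), 0L),
                       amplitude = vapply(events, `[[`, 0, "amplitude"),
                       is_distractor = vapply(events, `[[`, TRUE,
                                              "is_distractor"))
      df$pixels <- lapply(events, `[[`, "pixels")
      df
    } else {
      data.frame(cell = integer(0), onset = integer(0), area = integer(0),
                 amplitude = numeric(0), is_distractor = logical(0))
    }
    list(movie = ca_movie(frames, params$frame_interval, 1),
         vessel_mask = vessel, truth = truth)
  })
}
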