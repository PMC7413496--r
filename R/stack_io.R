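# Image stacks / movies with physical sampling metadata, TIFF I/O, and run
# configuration.
#
# Conventions (used everywhere in the package):
#   * stacks are 3D arrays indexed [z, y, x]; plane 1 is the shallowest;
#   * movies are 3D arrays indexed [t, y, x];
#   * physical steps are micrometres (lateral_step um/pixel, axial_step
#     um/plane) and seconds (frame_interval).
# TIFF files carry one page per plane/frame; physical metadata travels in a
# YAML sidecar `<path>.meta.yaml`, and explicit arguments always override it.
# Readers never fall back to silent default steps.

#' Construct an image stack
#'
#' @param voxels 3D numeric array indexed `[z, y, x]`, finite and >= 0.
#' @param lateral_step Lateral sampling, um/pixel, > 0.
#' @param axial_step Axial sampling, um/plane, > 0.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, lateral_step, axial_step) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array indexed [z, y, x]", call. = FALSE)
  if (any(dim(voxels) == 0L))
    stop("stack must have positive extent along every axis", call. = FALSE)
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("voxel intensities must be finite and >= 0", call. = FALSE)
  if (!is.numeric(lateral_step) || lateral_step <= 0 ||
      !is.numeric(axial_step) || axial_step <= 0)
    stop("lateral_step and axial_step must be > 0", call. = FALSE)
  structure(list(voxels = voxels, lateral_step = lateral_step,
                 axial_step = axial_step),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "Image stack: %d planes of %d x %d px (%.3g um/px lateral, %.3g um/plane axial)\n",
    d[1], d[2], d[3], x$lateral_step, x$axial_step))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_planes <- function(stack) dim(stack$voxels)[1]

stack_plane <- function(stack, k) stack$voxels[k, , , drop = TRUE]

#' Construct a time-lapse movie
#'
#' @param frames 3D numeric array indexed `[t, y, x]`, finite.
#' @param frame_interval Seconds per frame, > 0.
#' @param lateral_step Lateral sampling, um/pixel, > 0.
#' @return An object of class `ca_movie`.
#' @export
ca_movie <- function(frames, frame_interval = 1, lateral_step = 1) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be a 3D array indexed [t, y, x]", call. = FALSE)
  if (any(dim(frames) == 0L))
    stop("movie must have positive extent along every axis", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("frame intensities must be finite", call. = FALSE)
  if (frame_interval <= 0) stop("frame_interval must be > 0", call. = FALSE)
  if (lateral_step <= 0) stop("lateral_step must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_interval = frame_interval,
                 lateral_step = lateral_step),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Movie: %d frames of %d x %d px (%.3g s/frame)\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.ca_movie <- function(x) dim(x$frames)

sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_pages <- function(arr, path) {
  n <- dim(arr)[1]
  pages <- lapply(seq_len(n), function(k) arr[k, , , drop = TRUE])
  integerish <- all(vapply(pages, function(p)
    all(p == round(p)) && max(p) <= 65535, logical(1)))
  if (integerish) {
    scale <- 65535
    bits <- 16L
  } else {
    scale <- max(1, max(arr))
    bits <- 32L
  }
  tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                  bits.per.sample = bits, compression = "none")
  list(scale = scale, bits = bits)
}

read_pages <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("cannot read TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  ref <- dims[[1]]
  for (k in seq_along(dims))
    if (!identical(dims[[k]], ref))
      stop("TIFF '", path, "': page ", k, " has shape ",
           paste(dims[[k]], collapse = "x"), ", expected ",
           paste(ref, collapse = "x"), call. = FALSE)
  arr <- array(0, dim = c(length(pages), ref[1], ref[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  arr
}

#' Write an image stack as a multi-page TIFF
#'
#' One page per z-plane, shallowest first. Integer-valued stacks (maximum
#' at most 65535) are stored losslessly as 16-bit samples; other stacks as
#' 32-bit floats scaled by the stack maximum. The physical steps and the
#' intensity scale are recorded in a YAML sidecar `<path>.meta.yaml`.
#'
#' @param stack An [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  enc <- write_pages(stack$voxels, path)
  yaml::write_yaml(list(kind = "stack",
                        lateral_step_um = stack$lateral_step,
                        axial_step_um = stack$axial_step,
                        intensity_scale = enc$scale,
                        bits_per_sample = enc$bits),
                   sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' Pages are taken as z ascending. Physical steps are taken from explicit
#' arguments when given, otherwise from the YAML sidecar written by
#' [write_stack()]; if neither is available the call fails rather than
#' assuming default sampling.
#'
#' @param path TIFF file path.
#' @param lateral_step,axial_step Optional explicit sampling (um), which
#'   overrides sidecar metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, lateral_step = NULL, axial_step = NULL) {
  arr <- read_pages(path)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  scale <- meta$intensity_scale %||% 1
  arr <- arr * scale
  if (identical(meta$bits_per_sample, 16L) ||
      identical(meta$bits_per_sample, 16)) arr <- round(arr)
  lat <- lateral_step %||% meta$lateral_step_um
  axi <- axial_step %||% meta$axial_step_um
  if (is.null(lat) || is.null(axi))
    stop("physical steps for '", path, "' are not available: pass ",
         "lateral_step/axial_step explicitly or provide the metadata sidecar",
         call. = FALSE)
  image_stack(arr, lat, axi)
}

#' Write a movie as a multi-page TIFF
#'
#' @param movie A [ca_movie()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "ca_movie"))
  frames <- movie$frames
  offset <- min(frames)
  if (offset < 0) frames <- frames - offset else offset <- 0
  enc <- write_pages(frames, path)
  yaml::write_yaml(list(kind = "movie",
                        lateral_step_um = movie$lateral_step,
                        frame_interval_s = movie$frame_interval,
                        intensity_scale = enc$scale,
                        intensity_offset = offset,
                        bits_per_sample = enc$bits),
                   sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF as a movie
#'
#' @param path TIFF file path.
#' @param frame_interval,lateral_step Optional explicit metadata overriding
#'   the sidecar.
#' @return A [ca_movie()].
#' @export
read_movie <- function(path, frame_interval = NULL, lateral_step = NULL) {
  arr <- read_pages(path)
  meta <- if (file.exists(sidecar_path(path)))
    yaml::read_yaml(sidecar_path(path)) else list()
  arr <- arr * (meta$intensity_scale %||% 1)
  if (identical(meta$bits_per_sample, 16L) ||
      identical(meta$bits_per_sample, 16)) arr <- round(arr)
  arr <- arr + (meta$intensity_offset %||% 0)
  fi <- frame_interval %||% meta$frame_interval_s
  lat <- lateral_step %||% meta$lateral_step_um
  if (is.null(fi) || is.null(lat))
    stop("movie metadata for '", path, "' is not available: pass ",
         "frame_interval/lateral_step explicitly or provide the sidecar",
         call. = FALSE)
  ca_movie(arr, frame_interval = fi, lateral_step = lat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_config_schema <- function() {
  list(
    seed          = list(default = 1L,    check = function(v) is.numeric(v)),
    fill_mode     = list(default = "overfill",
                         check = function(v) v %in% c("overfill", "underfill")),
    immersion_ri  = list(default = 1.33,
                         check = function(v) is.numeric(v) && v >= 1.30 && v <= 1.40),
    depth_um      = list(default = 100,
                         check = function(v) is.numeric(v) && all(v >= 0)),
    n_beads       = list(default = 15,
                         check = function(v) is.numeric(v) && all(v >= 1)),
    mode          = list(default = "free_center",
                         check = function(v) v %in% c("free_center", "fixed_center")),
    min_area      = list(default = 20,
                         check = function(v) is.numeric(v) && v >= 0),
    connectivity  = list(default = 8,
                         check = function(v) v %in% c(4, 8)),
    k_lowest      = list(default = 100,
                         check = function(v) is.numeric(v) && v >= 1),
    min_separation_um = list(default = 2,
                             check = function(v) is.numeric(v) && v > 0))
}

#' Load and validate a run configuration
#'
#' Reads a flat key-value YAML file, rejects unknown and duplicated keys,
#' validates ranges, and fills defaults (for example `min_area` 20 and
#' `k_lowest` 100). All violations are reported together.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keys <- sub(":.*$", "", grep("^[A-Za-z0-9_]+\\s*:", lines, value = TRUE))
  keys <- trimws(keys)
  problems <- character(0)
  dups <- unique(keys[duplicated(keys)])
  if (length(dups))
    stop("invalid run configuration:\n  ",
         paste(paste0("duplicate key: ", dups), collapse = "\n  "),
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  schema <- run_config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key: ", unknown))
  for (key in names(schema)) {
    if (is.null(cfg[[key]])) {
      cfg[[key]] <- schema[[key]]$default
    } else if (!isTRUE(schema[[key]]$check(cfg[[key]]))) {
      problems <- c(problems,
                    paste0("out-of-range or ill-typed value for '", key, "'"))
    }
  }
  if (length(problems))
    stop("invalid run configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(cfg[names(schema)], class = "run_config")
}

#' Serialize a run configuration
#'
#' @param config A `run_config` (see [load_run_config()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
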