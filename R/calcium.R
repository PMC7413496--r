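# Spontaneous calcium-activity extraction: vessel-background subtraction,
# minimum-intensity-projection baseline, per-frame Otsu binarisation,
# connected components, and the >20-pixel area filter.

#' Subtract the blood-vessel background from a movie
#'
#' The scalar mean intensity of the vessel pixels, pooled over all frames,
#' is subtracted from every pixel of every frame; results are clipped at 0.
#'
#' @param movie A [ca_movie()].
#' @param mask Logical y-by-x matrix, `TRUE` at vessel pixels (non-empty).
#' @return The background-subtracted [ca_movie()].
#' @export
subtract_vessel_background <- function(movie, mask) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  if (!is.matrix(mask) || !identical(dim(mask), d[2:3]))
    stop("vessel mask must be a matrix matching the frame shape",
         call. = FALSE)
  if (!any(mask))
    stop("vessel mask is empty", call. = FALSE)
  bg <- mean(apply(movie$frames, 1, function(fr) mean(fr[mask])))
  out <- movie$frames - bg
  out[out < 0] <- 0
  ca_movie(out, movie$frame_interval, movie$lateral_step)
}

#' Per-pixel baseline from the minimum intensity projection
#'
#' @param movie A [ca_movie()] with at least 2 frames (a single frame has
#'   no defined baseline).
#' @return y-by-x matrix of per-pixel temporal minima.
#' @export
baseline_min_projection <- function(movie) {
  stopifnot(inherits(movie, "ca_movie"))
  if (dim(movie$frames)[1] < 2)
    stop("baseline requires at least 2 frames", call. = FALSE)
  apply(movie$frames, c(2, 3), min)
}

#' Activity movie: frame-wise subtraction of the baseline
#'
#' @param movie A (vessel-subtracted) [ca_movie()].
#' @param baseline y-by-x baseline matrix, e.g. from
#'   [baseline_min_projection()].
#' @return A [ca_movie()] of per-pixel \eqn{\Delta F} values in counts.
#' @export
delta_f <- function(movie, baseline) {
  stopifnot(inherits(movie, "ca_movie"))
  d <- dim(movie$frames)
  if (!is.matrix(baseline) || !identical(dim(baseline), d[2:3]))
    stop("baseline shape does not match the movie frames", call. = FALSE)
  out <- movie$frames
  for (t in seq_len(d[1])) out[t, , ] <- out[t, , ] - baseline
  structure(list(frames = out, frame_interval = movie$frame_interval,
                 lateral_step = movie$lateral_step),
            class = "ca_movie")
}

#' Otsu threshold of an image
#'
#' Histogram-based Otsu threshold: `n_bins` equal-width bins over the
#' image's own range, split chosen to maximise the between-class variance;
#' ties resolved toward the lowest threshold. Foreground is `value >
#' threshold`.
#'
#' @param x Numeric matrix or vector.
#' @param n_bins Number of histogram bins.
#' @return Threshold value (upper edge of the last background bin).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  v <- as.vector(x)
  r <- range(v)
  if (r[1] == r[2])
    stop("Otsu threshold undefined for a constant image", call. = FALSE)
  breaks <- seq(r[1], r[2], length.out = n_bins + 1)
  bin <- pmin(n_bins, findInterval(v, breaks, rightmost.closed = TRUE))
  h <- tabulate(bin, nbins = n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(v, bin)
  sums[as.integer(rownames(agg))] <- agg
  n <- length(v)
  omega <- cumsum(h) / n              # class-0 probability at each split
  mu <- cumsum(sums) / n              # class-0 partial mean intensity
  mu_t <- mu[n_bins]
  t_cand <- seq_len(n_bins - 1)
  valid <- omega[t_cand] > 0 & omega[t_cand] < 1
  sigma_b <- rep(-Inf, n_bins - 1)
  sigma_b[valid] <- (mu_t * omega[t_cand][valid] - mu[t_cand][valid])^2 /
    (omega[t_cand][valid] * (1 - omega[t_cand][valid]))
  best <- which.max(sigma_b)  # which.max returns the first (lowest) maximum
  breaks[best + 1]
}

# Connected-component labelling of a logical matrix by iterative flood
# fill; connectivity 4 (edges) or 8 (edges + corners).
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  ny <- nrow(mask); nx <- ncol(mask)
  labels <- matrix(0L, ny, nx)
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  current <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- (cur - 1L) %% ny + 1L
      x <- (cur - 1L) %/% ny + 1L
      for (o in offs) {
        yy <- y + o[1]; xx <- x + o[2]
        if (yy < 1L || yy > ny || xx < 1L || xx > nx) next
        nb <- yy + (xx - 1L) * ny
        if (mask[nb] && labels[nb] == 0L) {
          labels[nb] <- current
          queue <- c(queue, nb)
        }
      }
    }
  }
  labels
}

#' Extract activity regions of interest from a \eqn{\Delta F} movie
#'
#' Per frame (the default), the frame's \eqn{\Delta F} values are binarised
#' at their Otsu threshold, foreground pixels are grouped into connected
#' components, and components with area strictly greater than `min_area`
#' pixels are kept. ROIs found on different frames are merged when their
#' pixel sets overlap, keeping the pixel union and the earliest frame.
#' Frames with constant \eqn{\Delta F} (Otsu undefined) are skipped with a
#' warning. Frames whose Otsu foreground covers more than
#' `max_foreground` of the field are also skipped: spontaneous transients
#' are spatially sparse, so a frame where the "foreground" is a third of
#' the image is a frame without a distinct foreground, in which Otsu has
#' merely split the noise distribution. In `"aggregate"` mode a single
#' Otsu threshold is computed on the per-pixel temporal maximum image
#' instead.
#'
#' @param dfmovie A [ca_movie()] of \eqn{\Delta F} values.
#' @param min_area Minimum ROI area (exclusive); the conventional value 20
#'   keeps areas of 21 pixels and larger.
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @param mode `"per_frame"` (default) or `"aggregate"`.
#' @param max_foreground Maximum fraction of a frame the binarised
#'   foreground may cover for the frame to contribute ROIs.
#' @return A list of ROIs, each a list with `pixels` (linear column-major
#'   indices into a frame), `area`, and `first_frame`. Metadata attributes
#'   `connectivity` and `mode` record the choices.
#' @export
extract_rois <- function(dfmovie, min_area = 20, connectivity = 8,
                         mode = c("per_frame", "aggregate"),
                         max_foreground = 0.10) {
  stopifnot(inherits(dfmovie, "ca_movie"))
  mode <- match.arg(mode)
  d <- dim(dfmovie$frames)
  rois <- list()
  add_components <- function(fg, frame_idx) {
    labels <- label_components(fg, connectivity)
    for (lab in seq_len(max(labels))) {
      px <- which(labels == lab)
      if (length(px) > min_area)
        rois[[length(rois) + 1L]] <<- list(pixels = px,
                                           area = length(px),
                                           first_frame = frame_idx)
    }
  }
  if (mode == "per_frame") {
    for (t in seq_len(d[1])) {
      frame <- dfmovie$frames[t, , ]
      if (max(frame) == min(frame)) {
        warning("frame ", t, " is constant; skipped (Otsu undefined)",
                call. = FALSE)
        next
      }
      thr <- otsu_threshold(frame)
      fg <- frame > thr
      if (mean(fg) > max_foreground) next  # no distinct sparse foreground
      add_components(fg, t)
    }
  } else {
    peak <- apply(dfmovie$frames, c(2, 3), max)
    if (max(peak) == min(peak)) {
      warning("aggregate image is constant; no ROIs", call. = FALSE)
      return(structure(list(), connectivity = connectivity, mode = mode))
    }
    thr <- otsu_threshold(peak)
    add_components(peak > thr, 1L)
  }
  # merge overlapping ROIs across frames (union pixels, earliest frame)
  merged <- list()
  for (roi in rois) {
    hit <- NULL
    for (i in seq_along(merged)) {
      if (length(intersect(merged[[i]]$pixels, roi$pixels))) {
        hit <- i
        break
      }
    }
    if (is.null(hit)) {
      merged[[length(merged) + 1L]] <- roi
    } else {
      merged[[hit]]$pixels <- union(merged[[hit]]$pixels, roi$pixels)
      merged[[hit]]$area <- length(merged[[hit]]$pixels)
      merged[[hit]]$first_frame <- min(merged[[hit]]$first_frame,
                                       roi$first_frame)
    }
  }
  # repeated merging until stable (a later ROI can bridge two earlier ones)
  repeat {
    n0 <- length(merged)
    out <- list()
    for (roi in merged) {
      hit <- NULL
      for (i in seq_along(out)) {
        if (length(intersect(out[[i]]$pixels, roi$pixels))) {
          hit <- i
          break
        }
      }
      if (is.null(hit)) out[[length(out) + 1L]] <- roi
      else {
        out[[hit]]$pixels <- union(out[[hit]]$pixels, roi$pixels)
        out[[hit]]$area <- length(out[[hit]]$pixels)
        out[[hit]]$first_frame <- min(out[[hit]]$first_frame, roi$first_frame)
      }
    }
    merged <- out
    if (length(merged) == n0) break
  }
  structure(merged, connectivity = connectivity, mode = mode)
}

#' Per-ROI activity traces
#'
#' Mean \eqn{\Delta F} over each ROI's pixels, per frame, with the maximum
#' over frames. When a baseline image is supplied, the ROI's baseline F
#' (mean baseline over its pixels) is attached.
#'
#' @param dfmovie A [ca_movie()] of \eqn{\Delta F} values.
#' @param rois ROI list from [extract_rois()].
#' @param baseline Optional y-by-x baseline image.
#' @return A list of traces, each with `delta_f` (per frame), `max_delta_f`,
#'   `area`, `first_frame`, and `baseline_f` (NA without a baseline).
#' @export
roi_traces <- function(dfmovie, rois, baseline = NULL) {
  stopifnot(inherits(dfmovie, "ca_movie"))
  d <- dim(dfmovie$frames)
  lapply(rois, function(roi) {
    tr <- vapply(seq_len(d[1]), function(t) {
      frame <- dfmovie$frames[t, , ]
      mean(frame[roi$pixels])
    }, numeric(1))
    list(delta_f = tr, max_delta_f = max(tr), area = roi$area,
         first_frame = roi$first_frame,
         baseline_f = if (is.null(baseline)) NA_real_
         else mean(baseline[roi$pixels]))
  })
}

#' Fold change of activity amplitude between two conditions
#'
#' Ratio of the mean maximum \eqn{\Delta F} of condition a's traces to
#' condition b's.
#'
#' @param traces_a,traces_b Trace lists from [roi_traces()] (non-empty).
#' @return Dimensionless ratio, a over b.
#' @export
condition_fold_change <- function(traces_a, traces_b) {
  if (!length(traces_a) || !length(traces_b))
    stop("both trace lists must be non-empty", call. = FALSE)
  num <- mean(vapply(traces_a, `[[`, numeric(1), "max_delta_f"))
  den <- mean(vapply(traces_b, `[[`, numeric(1), "max_delta_f"))
  if (den == 0) stop("denominator condition has zero mean amplitude",
                     call. = FALSE)
  num / den
}

#' Full activity-extraction pipeline for one movie
#'
#' Vessel-background subtraction, minimum-projection baseline,
#' \eqn{\Delta F}, ROI extraction and traces, in the standard order.
#'
#' @param movie A raw [ca_movie()].
#' @param vessel_mask Logical vessel mask.
#' @param min_area,connectivity,mode Passed to [extract_rois()].
#' @return A list with `rois`, `traces`, `baseline` and the \eqn{\Delta F}
#'   movie `dfmovie`.
#' @export
extract_activity <- function(movie, vessel_mask, min_area = 20,
                             connectivity = 8, mode = "per_frame") {
  sub <- subtract_vessel_background(movie, vessel_mask)
  baseline <- baseline_min_projection(sub)
  dfm <- delta_f(sub, baseline)
  rois <- extract_rois(dfm, min_area = min_area,
                       connectivity = connectivity, mode = mode)
  list(rois = rois, traces = roi_traces(dfm, rois, baseline),
       baseline = baseline, dfmovie = dfm)
}
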