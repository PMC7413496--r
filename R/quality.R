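# Background/signal estimation and Brenner-gradient contrast scoring for
# comparing imaging conditions over the same 3D region.

#' Lowest-pixel background estimate
#'
#' From each plane of the stack, the `k_lowest` lowest-intensity pixels are
#' taken (value ties are immaterial to the mean) and pooled across all
#' planes; the background is the pooled mean. For the canonical 21-plane
#' stack with `k_lowest = 100`, exactly 2100 pixels enter the mean. The
#' pooled pixel count is attached as attribute `"n_pooled"`.
#'
#' @param stack An [image_stack()].
#' @param k_lowest Pixels taken per plane; every plane must have at least
#'   this many pixels.
#' @return Background level (counts) with attribute `n_pooled`.
#' @export
estimate_background <- function(stack, k_lowest = 100) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  npix <- d[2] * d[3]
  if (npix < k_lowest)
    stop("each plane has ", npix, " pixels, fewer than k_lowest = ",
         k_lowest, call. = FALSE)
  pooled <- vapply(seq_len(d[1]), function(k) {
    v <- sort(as.vector(stack_plane(stack, k)), partial = k_lowest)
    sum(v[seq_len(k_lowest)])
  }, numeric(1))
  bg <- sum(pooled) / (d[1] * k_lowest)
  attr(bg, "n_pooled") <- d[1] * k_lowest
  bg
}

#' Background-subtracted signal intensity
#'
#' Per-plane mean raw intensity minus the background, and the mean of the
#' per-plane values. Negative per-plane signals (noise) are reported as-is.
#'
#' @param stack An [image_stack()].
#' @param background Background level, e.g. from [estimate_background()].
#' @return A list with `per_plane_signal` (one value per plane) and
#'   `mean_signal`.
#' @export
signal_intensity <- function(stack, background) {
  stopifnot(inherits(stack, "image_stack"), is.finite(background))
  d <- dim(stack$voxels)
  per_plane <- vapply(seq_len(d[1]), function(k)
    mean(stack_plane(stack, k)) - background, numeric(1))
  list(per_plane_signal = per_plane, mean_signal = mean(per_plane))
}

#' Brenner gradient of a plane
#'
#' Sum over all valid pixels of `(I(x + step, y) - I(x, y))^2`, horizontal
#' (x) differences only, with no normalisation by pixel count — consumers
#' that need per-pixel values normalise explicitly.
#'
#' @param plane 2D numeric matrix (y by x).
#' @param step Pixel offset of the difference (classical value 2).
#' @return Non-negative focus/contrast score.
#' @examples
#' brenner_gradient(matrix(rep(c(0, 0, 1, 1), each = 4), 4, 4))  # 8
#' @export
brenner_gradient <- function(plane, step = 2) {
  if (!is.matrix(plane) || ncol(plane) <= step)
    stop("plane must be a matrix wider than the Brenner step (", step, ")",
         call. = FALSE)
  diffs <- plane[, (1 + step):ncol(plane), drop = FALSE] -
    plane[, seq_len(ncol(plane) - step), drop = FALSE]
  sum(diffs^2)
}

#' Normalise contrast scores to a reference condition
#'
#' @param values Per-condition Brenner sums (or any positive scores).
#' @param reference_index Index of the reference condition; it maps to 1.
#' @return `values / values[reference_index]`.
#' @export
normalized_contrast <- function(values, reference_index = 1) {
  ref <- values[reference_index]
  if (!is.finite(ref) || ref == 0)
    stop("reference contrast value must be nonzero", call. = FALSE)
  values / ref
}

#' Image-quality report for a stack
#'
#' Background (lowest-pixel rule), per-plane background-subtracted signal,
#' and per-plane Brenner gradient.
#'
#' @param stack An [image_stack()].
#' @param k_lowest Pixels per plane for the background estimate.
#' @param brenner_step Brenner pixel offset.
#' @return An object of class `quality_report`.
#' @export
quality_report <- function(stack, k_lowest = 100, brenner_step = 2) {
  bg <- estimate_background(stack, k_lowest)
  sig <- signal_intensity(stack, bg)
  bren <- vapply(seq_len(n_planes(stack)), function(k)
    brenner_gradient(stack_plane(stack, k), brenner_step), numeric(1))
  structure(list(background = as.numeric(bg),
                 n_pooled = attr(bg, "n_pooled"),
                 per_plane_signal = sig$per_plane_signal,
                 mean_signal = sig$mean_signal,
                 brenner_per_plane = bren,
                 mean_brenner = mean(bren)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(
    "Quality report: background %.3g (%d px pooled), mean signal %.4g, mean Brenner %.4g over %d planes\n",
    x$background, x$n_pooled, x$mean_signal, x$mean_brenner,
    length(x$per_plane_signal)))
  invisible(x)
}

#' Tabulate a quality report
#'
#' One row per plane plus a summary row, as written by the pipeline stage.
#'
#' @param report A [quality_report()].
#' @return A data.frame with columns `plane`, `signal`, `brenner`.
#' @export
as.data.frame.quality_report <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  n <- length(x$per_plane_signal)
  data.frame(plane = c(seq_len(n), NA),
             signal = c(x$per_plane_signal, x$mean_signal),
             brenner = c(x$brenner_per_plane, x$mean_brenner))
}
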