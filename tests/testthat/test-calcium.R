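make_movie <- function(arr) ca_movie(arr, frame_interval = 1)

test_that("vessel background subtraction removes the pooled vessel mean", {
  arr <- array(2, c(3, 8, 8))
  arr[2, 5, 5] <- 25
  mv <- make_movie(arr)
  mask <- matrix(FALSE, 8, 8)
  mask[, 1:2] <- TRUE
  out <- subtract_vessel_background(mv, mask)
  expect_equal(out$frames[2, 5, 5], 23)
  expect_equal(out$frames[1, 4, 4], 0)
  # all-zero movie unchanged
  z <- make_movie(array(0, c(2, 8, 8)))
  expect_equal(subtract_vessel_background(z, mask)$frames, z$frames)
  # full-frame mask on a constant movie: everything zero
  allm <- matrix(TRUE, 8, 8)
  cst <- make_movie(array(6, c(2, 8, 8)))
  expect_true(all(subtract_vessel_background(cst, allm)$frames == 0))
  expect_error(subtract_vessel_background(mv, matrix(FALSE, 8, 8)), "empty")
})

test_that("baseline is the per-pixel temporal minimum", {
  arr <- array(0, c(3, 2, 2))
  arr[, 1, 1] <- c(10, 25, 12)
  arr[, 2, 2] <- c(4, 4, 4)
  mv <- make_movie(arr)
  base <- baseline_min_projection(mv)
  expect_equal(base[1, 1], 10)
  expect_equal(base[2, 2], 4)
  # a very bright frame does not move the minimum
  arr2 <- arr
  arr2[2, , ] <- 1e6
  expect_equal(baseline_min_projection(make_movie(arr2))[1, 1], 10)
  expect_error(baseline_min_projection(make_movie(array(0, c(1, 2, 2)))),
               "2 frames")
})

test_that("delta F composes vessel and baseline subtraction as specified", {
  # raw 25, vessel mean 2, pixel minimum (after vessel subtraction) 8
  arr <- array(2, c(2, 4, 4))
  arr[, 2, 2] <- c(10, 25)
  mv <- make_movie(arr)
  mask <- matrix(FALSE, 4, 4)
  mask[, 1] <- TRUE
  sub <- subtract_vessel_background(mv, mask)
  base <- baseline_min_projection(sub)
  expect_equal(base[2, 2], 8)
  dfm <- delta_f(sub, base)
  expect_equal(dfm$frames[2, 2, 2], 15)  # (25 - 2) - 8
  expect_true(all(apply(dfm$frames, c(2, 3), min) == 0))
  expect_equal(delta_f(sub, sub$frames[1, , ])$frames[1, , ],
               matrix(0, 4, 4))
  expect_error(delta_f(sub, matrix(0, 2, 2)), "shape")
})

test_that("Otsu threshold matches the exhaustive between-class scan", {
  set.seed(15)
  for (i in 1:12) {
    img <- matrix(sample(0:255, 128, replace = TRUE), 8, 16)
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
  # clearly bimodal image: the threshold separates the two modes exactly
  # (ties across the empty gap resolve to the lowest threshold)
  set.seed(20)
  bim <- c(rnorm(200, 20, 2), rnorm(100, 200, 4))
  thr <- otsu_threshold(bim)
  expect_equal(sum(bim > thr), 100)
  expect_lt(thr, 190)
  expect_error(otsu_threshold(matrix(1, 4, 4)), "constant")
})

test_that("connected components agree with an igraph oracle", {
  skip_if_not_installed("igraph")
  set.seed(16)
  for (conn in c(4, 8)) for (i in 1:6) {
    mask <- matrix(runif(15 * 17) < 0.4, 15, 17)
    labels <- focalmetry:::label_components(mask, conn)
    px <- which(mask)
    if (!length(px)) next
    coords <- cbind((px - 1) %% 15 + 1, (px - 1) %/% 15 + 1)
    edges <- NULL
    for (a in seq_along(px)) for (b in seq_along(px)) {
      if (a >= b) next
      dy <- abs(coords[a, 1] - coords[b, 1])
      dx <- abs(coords[a, 2] - coords[b, 2])
      adj <- if (conn == 4) dy + dx == 1 else max(dy, dx) == 1
      if (adj) edges <- rbind(edges, c(a, b))
    }
    g <- igraph::graph_from_edgelist(if (is.null(edges))
      matrix(0L, 0, 2) else edges, directed = FALSE)
    g <- igraph::add_vertices(g, length(px) - igraph::vcount(g))
    comp <- igraph::components(g)
    expect_equal(max(labels), comp$no)
    # identical partitions up to label names
    expect_equal(length(unique(paste(labels[px], comp$membership))),
                 comp$no)
  }
})

test_that("ROI extraction keeps >20-pixel events and drops distractors", {
  p30 <- calcium_movie_params(n_cells = 1, n_events = 1,
                              event_area = c(30, 30), n_distractors = 0,
                              noise_sd = 0, poisson = FALSE, seed = 51)
  sim <- generate_calcium_movie(p30)
  act <- quiet_extract(sim$movie, sim$vessel_mask)
  expect_length(act$rois, 1)
  expect_equal(act$rois[[1]]$area, 30)
  expect_setequal(act$rois[[1]]$pixels, sim$truth$pixels[[1]])

  p15 <- calcium_movie_params(n_cells = 1, n_events = 0,
                              n_distractors = 1,
                              distractor_area = c(15, 15),
                              noise_sd = 0, poisson = FALSE, seed = 52)
  sim15 <- generate_calcium_movie(p15)
  expect_equal(sim15$truth$area, 15)
  act15 <- quiet_extract(sim15$movie, sim15$vessel_mask)
  expect_length(act15$rois, 0)

  # two simultaneous disjoint events in different cells: two ROIs
  p2 <- calcium_movie_params(n_cells = 2, n_events = 1,
                             event_area = c(25, 25), n_distractors = 0,
                             noise_sd = 0, poisson = FALSE, seed = 53)
  sim2 <- generate_calcium_movie(p2)
  act2 <- quiet_extract(sim2$movie, sim2$vessel_mask)
  expect_length(act2$rois, 2)
})

test_that("min_area 0 extraction is a superset of the filtered one", {
  p <- calcium_movie_params(n_cells = 2, n_events = 1, n_distractors = 2,
                            seed = 54)
  sim <- generate_calcium_movie(p)
  sub <- subtract_vessel_background(sim$movie, sim$vessel_mask)
  dfm <- delta_f(sub, baseline_min_projection(sub))
  all_rois <- suppressWarnings(extract_rois(dfm, min_area = 0))
  filt <- suppressWarnings(extract_rois(dfm, min_area = 20))
  all_px <- unlist(lapply(all_rois, `[[`, "pixels"))
  for (roi in filt) expect_true(all(roi$pixels %in% all_px))
  expect_gte(length(all_rois), length(filt))
})

test_that("ROI count ignores a constant offset added before processing", {
  p <- calcium_movie_params(n_cells = 2, n_events = 1, n_distractors = 1,
                            noise_sd = 0, poisson = FALSE, seed = 55)
  sim <- generate_calcium_movie(p)
  act0 <- quiet_extract(sim$movie, sim$vessel_mask)
  shifted <- ca_movie(sim$movie$frames + 11, sim$movie$frame_interval,
                      sim$movie$lateral_step)
  act1 <- quiet_extract(shifted, sim$vessel_mask)
  expect_equal(length(act1$rois), length(act0$rois))
})

test_that("constant frames are skipped with a warning, not an error", {
  arr <- array(0, c(2, 32, 32))
  arr[2, 3:7, 3:7] <- 5  # one constant frame, one sparse active frame
  dfm <- make_movie(arr)
  expect_warning(rois <- extract_rois(dfm, min_area = 20), "constant")
  expect_length(rois, 1)
  expect_equal(rois[[1]]$area, 25)
})

test_that("traces report per-frame means and the event amplitude", {
  arr <- array(0, c(4, 6, 6))
  arr[, 2, 3] <- c(0, 5, 2, 0)
  dfm <- make_movie(arr)
  roi <- list(list(pixels = 2 + (3 - 1) * 6, area = 1L, first_frame = 2L))
  tr <- roi_traces(dfm, roi)
  expect_equal(tr[[1]]$delta_f, c(0, 5, 2, 0))
  expect_equal(tr[[1]]$max_delta_f, 5)
  # amplitude recovery on a rendered event (noise off)
  p <- calcium_movie_params(n_cells = 1, n_events = 1,
                            event_area = c(30, 30), n_distractors = 0,
                            event_amplitude = 1, baseline_f = 50,
                            noise_sd = 0, poisson = FALSE, seed = 57)
  sim <- generate_calcium_movie(p)
  act <- quiet_extract(sim$movie, sim$vessel_mask)
  expect_equal(act$traces[[1]]$max_delta_f, 50, tolerance = 0.1)
})

test_that("fold change is the ratio of mean maximum amplitudes", {
  a <- list(list(max_delta_f = 4), list(max_delta_f = 8))
  b <- list(list(max_delta_f = 1), list(max_delta_f = 2))
  expect_equal(condition_fold_change(a, b), 4)
  expect_equal(condition_fold_change(a, a), 1)
  expect_error(condition_fold_change(a, list()), "non-empty")
})
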