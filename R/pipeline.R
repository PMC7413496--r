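# End-to-end runs: simulate -> measure -> summarise -> test. Each stage is
# exported on its own; these drivers wire them together, write tabular
# outputs and a run manifest, and keep all randomness derived from one seed.

derive_seed <- function(seed, stage, item = 0L) {
  # deterministic per-stage substreams; keep well below 2^31
  (as.integer(seed) * 97L + stage * 7919L + item) %% 2000000011L
}

write_manifest <- function(out_dir, seed, files) {
  manifest <- list(seed = seed,
                   package_version =
                     as.character(utils::packageVersion("focalmetry")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = lapply(files, function(f)
                     list(path = f, md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Evaluate focal volumes across imaging conditions
#'
#' For every condition (fill mode, immersion RI, depth) this simulates
#' single-bead stacks at the condition's preset focal-volume widths,
#' detects and measures the beads, summarises per condition, and runs
#' pairwise Welch tests (Bonferroni-corrected) of each RI against the
#' water-immersion reference (n = 1.33) within each fill mode and depth.
#'
#' @param conditions data.frame with columns `fill_mode`, `immersion_ri`,
#'   `depth`, `n_beads`.
#' @param mode Gaussian-fit mode, `"free_center"` (clean preparations) or
#'   `"fixed_center"` (motion-affected in vivo presumption).
#' @param seed Integer seed driving all randomness.
#' @param use_ri_model Inflate the presets with the phenomenological RI
#'   mismatch model ([psf_model()]); by default the presets are used
#'   directly.
#' @param bead_params Base [bead_field_params()] for the simulated stacks
#'   (the per-stack seed and `n_beads = 1` are set internally).
#' @param out_dir Optional directory for TSV outputs and a manifest.
#' @return An object of class `psf_evaluation`: per-bead measurements,
#'   per-condition summaries, and the Welch/Bonferroni test table.
#' @export
run_psf_evaluation <- function(conditions, mode = "free_center", seed = 1,
                               use_ri_model = FALSE,
                               bead_params = bead_field_params(),
                               out_dir = NULL) {
  if (!is.data.frame(conditions) || nrow(conditions) == 0)
    stop("conditions must be a non-empty data.frame", call. = FALSE)
  needed <- c("fill_mode", "immersion_ri", "depth", "n_beads")
  if (!all(needed %in% names(conditions)))
    stop("conditions must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  beads <- NULL
  summaries <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- imaging_condition(conditions$fill_mode[ci],
                              conditions$immersion_ri[ci],
                              conditions$depth[ci])
    psf <- if (use_ri_model) psf_model(cond) else psf_preset(cond)
    rows <- NULL
    for (b in seq_len(conditions$n_beads[ci])) {
      p <- bead_params
      p$n_beads <- 1L
      p$seed <- derive_seed(seed, ci, b)
      sim <- generate_bead_stack(p, psf)
      det <- detect_beads(sim$stack, min_separation = p$min_separation,
                          smooth_fwhm = psf)
      det <- det[det$isolation_ok, , drop = FALSE]
      if (nrow(det) == 0) next
      det <- det[which.max(det$peak_intensity), , drop = FALSE]
      m <- measure_bead(sim$stack, det, mode)
      rows <- rbind(rows, cbind(condition = ci, bead = b, m))
    }
    if (is.null(rows))
      stop("no beads detected for condition ", ci, call. = FALSE)
    beads <- rbind(beads, rows)
    summaries[[ci]] <- summarize_condition(rows, cond)
  }
  # Welch tests of each RI against the 1.33 reference per fill mode x depth
  tests <- NULL
  key <- paste(conditions$fill_mode, conditions$depth)
  for (grp in unique(key)) {
    members <- which(key == grp)
    ref <- members[conditions$immersion_ri[members] == 1.33]
    if (length(ref) != 1) next
    others <- setdiff(members, ref)
    if (!length(others)) next
    ps <- numeric(0)
    rows <- NULL
    for (m2 in others) {
      xa <- beads$fwhm_z[beads$condition == m2]
      xb <- beads$fwhm_z[beads$condition == ref]
      ht <- welch_t_test(xa, xb)
      ps <- c(ps, ht$p_value)
      rows <- rbind(rows, data.frame(
        fill_mode = conditions$fill_mode[m2],
        depth = conditions$depth[m2],
        immersion_ri = conditions$immersion_ri[m2],
        reference_ri = 1.33,
        statistic = ht$statistic, df = ht$degrees_of_freedom,
        p_value = ht$p_value))
    }
    rows$adjusted_p <- bonferroni(ps, length(ps))
    tests <- rbind(tests, rows)
  }
  summary_df <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    data.frame(fill_mode = conditions$fill_mode[i],
               immersion_ri = conditions$immersion_ri[i],
               depth = conditions$depth[i],
               mean_fwhm_xy = s$mean_fwhm_xy, sem_fwhm_xy = s$sem_fwhm_xy,
               mean_fwhm_z = s$mean_fwhm_z, sem_fwhm_z = s$sem_fwhm_z,
               n_beads = s$n_beads)
  }))
  out <- structure(list(beads = beads, summaries = summaries,
                        summary_table = summary_df, tests = tests,
                        conditions = conditions, mode = mode, seed = seed),
                   class = "psf_evaluation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(write_tsv(beads, file.path(out_dir, "beads.tsv")),
               write_tsv(summary_df, file.path(out_dir, "summary.tsv")))
    if (!is.null(tests))
      files <- c(files, write_tsv(tests, file.path(out_dir, "tests.tsv")))
    write_manifest(out_dir, seed, files)
  }
  out
}

#' @export
print.psf_evaluation <- function(x, ...) {
  cat("Focal-volume evaluation (", x$mode, " mode, seed ", x$seed, ")\n",
      sep = "")
  print(x$summary_table, row.names = FALSE)
  invisible(x)
}

#' Compare image quality across conditions over a shared scene
#'
#' Simulates one neurite-like scene and images it under every condition's
#' focal-volume widths, then scores background, signal and per-plane
#' Brenner contrast; runs a Friedman test across conditions with planes as
#' blocks, DSCF all-pairs post-hoc comparisons on the per-plane Brenner
#' values, and normalises contrast to the chosen reference condition.
#'
#' @param conditions data.frame with `fill_mode`, `immersion_ri`, `depth`
#'   (one row per condition).
#' @param reference_index Condition whose contrast maps to 1.
#' @param seed Integer seed (the scene is shared across conditions).
#' @param structure_params Base [structure_field_params()].
#' @param k_lowest Background pool size per plane.
#' @param out_dir Optional output directory.
#' @return An object of class `quality_comparison`.
#' @export
run_quality_comparison <- function(conditions, reference_index = 1, seed = 1,
                                   structure_params = structure_field_params(),
                                   k_lowest = 100, out_dir = NULL) {
  if (!is.data.frame(conditions) || nrow(conditions) < 2)
    stop("need at least 2 conditions", call. = FALSE)
  reports <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- imaging_condition(conditions$fill_mode[ci],
                              conditions$immersion_ri[ci],
                              conditions$depth[ci])
    psf <- psf_model(cond)
    p <- structure_params
    p$seed <- derive_seed(seed, 100L)  # scene shared across conditions
    sim <- generate_structure_stack(p, psf)
    reports[[ci]] <- quality_report(sim$stack, k_lowest = k_lowest)
  }
  plane_counts <- vapply(reports, function(r) length(r$brenner_per_plane), 0L)
  if (length(unique(plane_counts)) != 1)
    stop("conditions have mismatched plane counts", call. = FALSE)
  bren <- vapply(reports, function(r) r$brenner_per_plane,
                 numeric(plane_counts[1]))
  fr <- friedman_test(bren)
  dscf <- dscf_all_pairs(as.list(as.data.frame(bren)))
  contrast <- normalized_contrast(vapply(reports, function(r)
    r$mean_brenner, numeric(1)), reference_index)
  tab <- data.frame(fill_mode = conditions$fill_mode,
                    immersion_ri = conditions$immersion_ri,
                    depth = conditions$depth,
                    background = vapply(reports, function(r)
                      r$background, numeric(1)),
                    mean_signal = vapply(reports, function(r)
                      r$mean_signal, numeric(1)),
                    mean_brenner = vapply(reports, function(r)
                      r$mean_brenner, numeric(1)),
                    normalized_contrast = contrast)
  out <- structure(list(reports = reports, table = tab, friedman = fr,
                        dscf = dscf, reference_index = reference_index,
                        seed = seed),
                   class = "quality_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_tsv(tab, file.path(out_dir, "quality.tsv"))
    files <- c(files, write_tsv(dscf$pairs,
                                file.path(out_dir, "dscf_pairs.tsv")))
    write_manifest(out_dir, seed, files)
  }
  out
}

#' @export
print.quality_comparison <- function(x, ...) {
  cat("Image-quality comparison (seed ", x$seed, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  print(x$friedman)
  invisible(x)
}

#' Compare spontaneous-activity extraction between two conditions
#'
#' Simulates (or accepts) a pair of calcium movies labelled a and b, runs
#' the full extraction pipeline on each, and reports ROI counts per
#' condition and the fold change of mean maximum \eqn{\Delta F} (a over b).
#'
#' @param params_a,params_b [calcium_movie_params()] for the two
#'   conditions; their `seed` fields are overridden from `seed` so that the
#'   two movies share scene geometry.
#' @param seed Integer seed.
#' @param min_area,connectivity Passed to [extract_rois()].
#' @param out_dir Optional output directory.
#' @return An object of class `activity_comparison` with elements
#'   `rois_a`, `rois_b`, `fold_change`, `table`.
#' @export
run_activity_analysis <- function(params_a, params_b, seed = 1,
                                  min_area = 20, connectivity = 8,
                                  out_dir = NULL) {
  stopifnot(inherits(params_a, "calcium_movie_params"),
            inherits(params_b, "calcium_movie_params"))
  params_a$seed <- derive_seed(seed, 200L)
  params_b$seed <- derive_seed(seed, 200L)  # shared scene geometry
  sim_a <- generate_calcium_movie(params_a)
  sim_b <- generate_calcium_movie(params_b)
  act_a <- extract_activity(sim_a$movie, sim_a$vessel_mask,
                            min_area = min_area,
                            connectivity = connectivity)
  act_b <- extract_activity(sim_b$movie, sim_b$vessel_mask,
                            min_area = min_area,
                            connectivity = connectivity)
  fc <- condition_fold_change(act_a$traces, act_b$traces)
  tab <- data.frame(condition = c("a", "b"),
                    n_rois = c(length(act_a$rois), length(act_b$rois)),
                    mean_max_delta_f = c(
                      mean(vapply(act_a$traces, `[[`, 0, "max_delta_f")),
                      mean(vapply(act_b$traces, `[[`, 0, "max_delta_f"))))
  out <- structure(list(activity_a = act_a, activity_b = act_b,
                        truth_a = sim_a$truth, truth_b = sim_b$truth,
                        fold_change = fc, table = tab, seed = seed),
                   class = "activity_comparison")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- write_tsv(tab, file.path(out_dir, "activity.tsv"))
    roi_tab <- function(act, label) {
      if (!length(act$rois))
        return(data.frame(condition = character(0), roi = integer(0),
                          area = integer(0), first_frame = integer(0),
                          max_delta_f = numeric(0)))
      data.frame(condition = label, roi = seq_along(act$rois),
                 area = vapply(act$rois, `[[`, 0L, "area"),
                 first_frame = vapply(act$rois, `[[`, 0L, "first_frame"),
                 max_delta_f = vapply(act$traces, `[[`, 0, "max_delta_f"))
    }
    files <- c(files, write_tsv(rbind(roi_tab(act_a, "a"),
                                      roi_tab(act_b, "b")),
                                file.path(out_dir, "rois.tsv")))
    write_manifest(out_dir, seed, files)
  }
  out
}

#' @export
print.activity_comparison <- function(x, ...) {
  cat("Activity comparison (seed ", x$seed, "): fold change ",
      sprintf("%.3g", x$fold_change), " (a over b)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
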