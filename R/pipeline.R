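#' Default dual thresholds implied by a simulation config
#'
#' Midpoint thresholds: the whole-cell threshold halfway between background
#' and the lamellipodium intensity, the body threshold halfway between the
#' lamellipodium and body intensities.
#'
#' @param config A [simulation_config()].
#' @return Named vector `c(t_cell, t_body)`.
#' @export
config_thresholds <- function(config) {
  c(t_cell = config$lamellipodium_intensity / 2,
    t_body = (config$lamellipodium_intensity + config$body_intensity) / 2)
}

#' Match detections to ground-truth cells
#'
#' Per frame, each detection is matched to the nearest ground-truth cell
#' within `max_dist`; matched truth identity, phenotype and state are
#' appended.
#'
#' @param detections Detection (or track) data frame.
#' @param truth Ground-truth table from [run_simulation()].
#' @param max_dist Maximum centroid-to-truth distance (um).
#' @return The detections with `true_cell_id`, `true_phenotype`,
#'   `true_state` columns (`NA` where unmatched).
#' @export
match_to_truth <- function(detections, truth, max_dist = 15) {
  detections$true_cell_id <- NA_integer_
  detections$true_phenotype <- NA_character_
  detections$true_state <- NA_character_
  if (nrow(detections) == 0) return(detections)
  for (f in unique(detections$frame)) {
    di <- which(detections$frame == f)
    tr <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(tr) == 0) next
    d2 <- outer(detections$x_um[di], tr$x_um, "-")^2 +
      outer(detections$y_um[di], tr$y_um, "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    ok <- sqrt(d2[cbind(seq_along(di), nearest)]) <= max_dist
    detections$true_cell_id[di[ok]] <- tr$cell_id[nearest[ok]]
    detections$true_phenotype[di[ok]] <- tr$phenotype[nearest[ok]]
    detections$true_state[di[ok]] <- tr$state[nearest[ok]]
  }
  detections
}

# detections synthesised directly from the ground-truth table (tracking on
# ground-truth centroids; bypasses rendering and segmentation)
truth_detections <- function(truth, config) {
  flags <- do.call(rbind, lapply(config$phenotypes, function(p)
    data.frame(phenotype = p$name, lurp = p$lurp_positive,
               mpeg = p$mpeg_positive)))
  i <- match(truth$phenotype, flags$phenotype)
  data.frame(frame = truth$frame, cell_label = truth$cell_id,
             x_um = truth$x_um, y_um = truth$y_um,
             wca_um2 = truth$whole_area_um2, cba_um2 = truth$body_area_um2,
             nla = truth$whole_area_um2 / truth$body_area_um2,
             length_um = 2 * sqrt(truth$whole_area_um2 / pi),
             lamellipodia = NA_integer_,
             intensity_lurp = ifelse(flags$lurp[i], config$body_intensity, 0),
             intensity_mpeg = ifelse(flags$mpeg[i], config$body_intensity, 0))
}

#' Run the full simulate-measure pipeline
#'
#' Orchestrates simulate, segment, track, kinematics and circular
#' statistics. With `render = TRUE` (default) the measurement runs on
#' rendered images; with `render = FALSE` tracking operates on ground-truth
#' centroids (fast path for replicate studies of the downstream
#' statistics).
#'
#' The directional analysis takes, for every track with at least two points
#' inside the analysis window, its net displacement vector over the window;
#' tracks whose net displacement stays below `min_net_displacement` are not
#' migrating (the tracking procedure follows migrating cells, and a cell
#' that has not moved by about one body size carries no meaningful
#' direction) and are excluded. Angles feed the Rayleigh test, circular
#' mean and rose histogram, and the wound bearing is reported alongside.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory; when given, all stage
#'   artifacts are written (TIFF stacks, truth/detections/tracks/kinematics
#'   CSV, JSON report, rose-histogram CSV).
#' @param seed Overrides `config$seed`.
#' @param render Render and segment images, or use the ground-truth fast
#'   path.
#' @param t_cell,t_body Dual thresholds; default [config_thresholds()].
#' @param min_track_points Minimum points for a track to enter kinematics
#'   (default 10).
#' @param window Analysis window `c(first_frame, last_frame)` for
#'   displacement vectors; default wound onset (or frame 1) to the last
#'   frame.
#' @param min_net_displacement Minimum net displacement (um) over the
#'   window for a track to count as migrating and enter the directional
#'   analysis; default 15 (about one cell body size).
#' @param mc_pvalue Also compute the Monte-Carlo Rayleigh p-value.
#' @param bin_width Rose-histogram bin width (degrees).
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL,
                         render = TRUE, t_cell = NULL, t_body = NULL,
                         min_track_points = 10, window = NULL,
                         min_net_displacement = 15,
                         mc_pvalue = FALSE, bin_width = 20) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("simulate", run_simulation(config, render = render))
  if (nrow(sim$truth) == 0) stop("[stage simulate] empty simulation")

  if (render) {
    th <- config_thresholds(config)
    if (is.null(t_cell)) t_cell <- th[["t_cell"]]
    if (is.null(t_body)) t_body <- th[["t_body"]]
    detections <- stage("segment",
      segment_sequence(sim$images, t_cell = t_cell, t_body = t_body))
    detections <- stage("segment", classify_channels(detections))
  } else {
    detections <- stage("segment", truth_detections(sim$truth, config))
    detections <- stage("segment", classify_channels(detections))
  }

  tracks <- stage("track", build_tracks(detections))
  tracks <- stage("track", filter_tracks(tracks, max(2, min_track_points)))
  kin <- stage("kinematics", track_kinematics(tracks, config$frame_interval))

  if (is.null(window)) {
    w0 <- if (is.finite(config$wound_onset_frame))
      max(1, config$wound_onset_frame) else 1
    window <- c(w0, config$n_frames)
  }
  win_pts <- tracks[tracks$frame >= window[1] & tracks$frame <= window[2], ,
                    drop = FALSE]
  disp <- stage("circstats", {
    ids <- unique(win_pts$track_id)
    rows <- lapply(ids, function(id) {
      tr <- win_pts[win_pts$track_id == id, , drop = FALSE]
      if (nrow(tr) < 2) return(NULL)
      nd <- net_displacement_vector(tr)
      if (sqrt(sum(nd^2)) < min_net_displacement) return(NULL)
      data.frame(track_id = id, dx = nd[["dx"]], dy = nd[["dy"]])
    })
    do.call(rbind, rows)
  })
  rayleigh <- NULL; mean_dir <- NA_real_; rose <- NULL; vectors <- NULL
  rayleigh_mc <- NULL
  if (!is.null(disp) && nrow(disp) >= 4) {
    vectors <- suppressWarnings(to_polar(disp$dx, disp$dy))
    if (nrow(vectors) >= 4) {
      rayleigh <- rayleigh_test(vectors$angle_deg)
      if (mc_pvalue)
        rayleigh_mc <- rayleigh_test(vectors$angle_deg, method = "mc")
      mean_dir <- tryCatch(circ_mean(vectors$angle_deg),
                           error = function(e) NA_real_)
      rose <- rose_histogram(vectors, bin_width = bin_width)
    }
  }

  report <- structure(list(
    config = config, seed = config$seed, render = render,
    thresholds = if (render) c(t_cell = t_cell, t_body = t_body) else NULL,
    truth = sim$truth, images = sim$images,
    detections = detections, tracks = tracks, kinematics = kin,
    vectors = vectors, rayleigh = rayleigh, rayleigh_mc = rayleigh_mc,
    circ_mean_deg = mean_dir, wound_bearing_deg = wound_bearing(config),
    rose = rose, window = window,
    counts = c(cells = length(unique(sim$truth$cell_id)),
               detections = nrow(detections),
               tracks = length(unique(tracks$track_id)),
               vectors = if (is.null(vectors)) 0L else nrow(vectors))
  ), class = "pipeline_report")

  if (!is.null(out_dir)) write_pipeline_outputs(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (seed %d%s)\n", x$seed,
              if (x$render) "" else ", ground-truth fast path"))
  cat(sprintf("  %d cells -> %d detections -> %d tracks -> %d displacement vectors\n",
              x$counts["cells"], x$counts["detections"], x$counts["tracks"],
              x$counts["vectors"]))
  if (!is.null(x$rayleigh)) {
    print(x$rayleigh)
    cat(sprintf("  circular mean %.1f deg, wound bearing %.1f deg\n",
                x$circ_mean_deg, x$wound_bearing_deg))
  }
  invisible(x)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$images))
    write_image_sequence(report$images, file.path(out_dir, "stack"))
  utils::write.csv(report$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(report$detections, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tracks, file.path(out_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$kinematics, file.path(out_dir, "kinematics.csv"),
                   row.names = FALSE)
  if (!is.null(report$rose)) {
    bw <- diff(report$rose$bin_edges[1:2])
    utils::write.csv(
      data.frame(bin_start = report$rose$bin_edges[-length(report$rose$bin_edges)],
                 bin_end = report$rose$bin_edges[-1],
                 count = report$rose$counts,
                 mean_magnitude = report$rose$mean_magnitude),
      file.path(out_dir, "rose.csv"), row.names = FALSE)
  }
  summary <- list(
    seed = report$seed,
    counts = as.list(report$counts),
    window = report$window,
    wound_bearing_deg = report$wound_bearing_deg,
    circ_mean_deg = report$circ_mean_deg,
    rayleigh = if (!is.null(report$rayleigh))
      report$rayleigh[c("n", "rbar", "z", "p_value")] else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Parameter-recovery table for a simulated run
#'
#' Compares, per phenotype, the generative parameters of a simulation with
#' what the measurement pipeline recovered: mean activated speed (from
#' track-average speeds over activated frames), mean whole-cell area, NLA,
#' subset composition and overall cell density.
#'
#' @param report A `pipeline_report` from [run_pipeline()] on a simulation.
#' @param tolerance Relative-error tolerance for the pass flag (density
#'   uses `1.5 * tolerance` to allow for boundary losses at realistic
#'   densities).
#' @return Data frame: `parameter`, `group`, `truth`, `estimate`,
#'   `rel_error`, `tolerance`, `pass`.
#' @export
recover_parameters <- function(report, tolerance = 0.10) {
  stopifnot(inherits(report, "pipeline_report"))
  if (is.null(report$truth) || nrow(report$truth) == 0)
    stop("missing ground truth: recovery needs a simulation-mode run")
  config <- report$config
  rows <- list()
  add <- function(parameter, group, truth, estimate, tol) {
    rel <- if (is.finite(truth) && truth != 0)
      abs(estimate - truth) / abs(truth) else NA_real_
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, group = group, truth = truth,
      estimate = estimate, rel_error = rel, tolerance = tol,
      pass = is.finite(rel) && rel <= tol)
  }

  dets <- match_to_truth(report$detections, report$truth)
  tracks <- match_to_truth(report$tracks, report$truth)

  for (p in config$phenotypes) {
    if (p$count == 0) next
    dp <- dets[!is.na(dets$true_phenotype) & dets$true_phenotype == p$name, ]
    if (nrow(dp) > 0) {
      add("mean_wca_um2", p$name, expected_whole_area(p), mean(dp$wca_um2),
          tolerance)
      add("mean_nla", p$name, expected_whole_area(p) / expected_body_area(p),
          mean(dp$nla), tolerance)
    }
    tp <- tracks[!is.na(tracks$true_phenotype) &
                   tracks$true_phenotype == p$name &
                   tracks$true_state == "activated", ]
    if (nrow(tp) > 0) {
      ids <- unique(tp$track_id)
      sp <- vapply(ids, function(id) {
        tr <- tp[tp$track_id == id, ]
        if (nrow(tr) < 5 || any(diff(sort(tr$frame)) != 1)) return(NA_real_)
        average_speed(tr, config$frame_interval)
      }, numeric(1))
      sp <- sp[is.finite(sp)]
      if (length(sp) >= 3)
        add("speed_mean_um_min", p$name, p$speed_mean, mean(sp), tolerance)
    }
  }

  # subset composition
  gen <- vapply(config$phenotypes, function(p) p$count, numeric(1))
  lab <- vapply(config$phenotypes, function(p) {
    if (p$lurp_positive && !p$mpeg_positive) "lurp_only"
    else if (p$lurp_positive && p$mpeg_positive) "double_positive"
    else if (p$mpeg_positive) "mpeg_only" else "unclassified"
  }, character(1))
  gen_frac <- tapply(gen, lab, sum) / sum(gen)
  meas <- subset_proportions(dets)
  for (s in names(meas)) {
    tg <- if (s %in% names(gen_frac)) unname(gen_frac[s]) else 0
    rows[[length(rows) + 1]] <- data.frame(
      parameter = "subset_fraction", group = s, truth = tg,
      estimate = unname(meas[s]),
      rel_error = NA_real_, tolerance = 0.02,
      pass = abs(meas[s] - tg) <= 0.02)   # absolute +/- 2 points
  }

  field_mm2 <- config$field_width * config$field_height / 1e6
  per_frame <- nrow(dets) / config$n_frames
  add("density_cells_mm2", "all", sum(gen) / field_mm2, per_frame / field_mm2,
      1.5 * tolerance)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
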