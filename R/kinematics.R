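#' Instantaneous (point) speeds along a track
#'
#' The point speed at each time point is the Euclidean displacement between
#' consecutive frames divided by the frame interval.
#'
#' @param track Data frame of one track with columns `frame, x_um, y_um`.
#' @param frame_interval Frame interval (min).
#' @return Numeric vector of speeds (um/min), one per consecutive frame
#'   pair.
#' @export
point_speeds <- function(track, frame_interval) {
  track <- track[order(track$frame), ]
  if (nrow(track) < 2) stop("point speeds need at least 2 track points")
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  steps / (diff(track$frame) * frame_interval)
}

#' Average speed of a track
#'
#' Total path length divided by elapsed time (the 1-h-block definition of
#' migration speed). Equals the mean of the point speeds when frames are
#' evenly spaced.
#'
#' @inheritParams point_speeds
#' @return Average speed (um/min).
#' @export
average_speed <- function(track, frame_interval) {
  track <- track[order(track$frame), ]
  if (nrow(track) < 2) stop("average speed needs at least 2 track points")
  steps <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  sum(steps) / ((max(track$frame) - min(track$frame)) * frame_interval)
}

#' Net displacement vector of a track
#'
#' @inheritParams point_speeds
#' @return Named numeric `c(dx, dy)` (um), last position minus first.
#' @export
net_displacement_vector <- function(track) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  c(dx = track$x_um[n] - track$x_um[1], dy = track$y_um[n] - track$y_um[1])
}

#' Kinematics table for a set of tracks
#'
#' @param tracks Track data frame from [build_tracks()].
#' @param frame_interval Frame interval (min).
#' @return Data frame per track: `track_id, n_points, path_length,
#'   net_displacement, dx, dy, average_speed, peak_speed` (the maximum
#'   point speed).
#' @export
track_kinematics <- function(tracks, frame_interval) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) return(NULL)
    ps <- point_speeds(tr, frame_interval)
    nd <- net_displacement_vector(tr)
    data.frame(track_id = id, n_points = nrow(tr),
               path_length = sum(ps) * frame_interval,
               net_displacement = sqrt(sum(nd^2)),
               dx = nd[["dx"]], dy = nd[["dy"]],
               average_speed = average_speed(tr, frame_interval),
               peak_speed = max(ps))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(track_id = integer(0), n_points = integer(0),
                      path_length = numeric(0), net_displacement = numeric(0),
                      dx = numeric(0), dy = numeric(0),
                      average_speed = numeric(0), peak_speed = numeric(0))
  rownames(out) <- NULL
  out
}

#' Activation time of a tracked cell
#'
#' A cell counts as activated at the first sustained displacement of more
#' than one body size: sliding windows of `window_frames` frames are
#' examined, and the activation frame is the start of the first run of
#' `window_frames` consecutive windows whose displacement (straight-line,
#' window start to window end) each exceeds `body_length`. The activation
#' time is the elapsed time from `wound_time` to that frame.
#'
#' @param track Data frame of one track (`frame, x_um, y_um`).
#' @param body_length Body size threshold (um); conventionally the
#'   cell-body equivalent diameter `2 * sqrt(CBA / pi)`.
#' @param wound_time Time of wounding (min, same clock as
#'   `(frame - 1) * frame_interval`).
#' @param frame_interval Frame interval (min).
#' @param window_frames Window width and required run length (frames).
#' @return Activation time in min, or `NA` if the cell never sustains such
#'   displacement.
#' @export
activation_time <- function(track, body_length, wound_time, frame_interval,
                            window_frames = 3) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  w <- window_frames
  if (n < 2 * w) return(NA_real_)
  x <- track$x_um; y <- track$y_um
  # displacement of window ending at index i (window start i - w)
  ends <- (w + 1):n
  disp <- sqrt((x[ends] - x[ends - w])^2 + (y[ends] - y[ends - w])^2)
  exceed <- disp > body_length
  run <- rle(exceed)
  pos <- cumsum(run$lengths) - run$lengths + 1L
  hit <- which(run$values & run$lengths >= w)
  if (length(hit) == 0) return(NA_real_)
  first_end_idx <- ends[pos[hit[1]]]          # index of first qualifying window end
  onset_frame <- track$frame[first_end_idx - w]  # window start = movement onset
  (onset_frame - 1) * frame_interval - wound_time
}

#' Proportions of classified subsets
#'
#' @param detections Classified detection data frame (see
#'   [classify_channels()]).
#' @return Named numeric vector of fractions over classified detections
#'   (`lurp_only`, `double_positive`, `mpeg_only`), summing to 1.
#' @export
subset_proportions <- function(detections) {
  if (!"subset" %in% names(detections))
    stop("detections must carry a subset column; run classify_channels first")
  keep <- detections$subset != "unclassified"
  n <- sum(keep)
  if (n == 0) stop("no classified detections")
  counts <- table(factor(detections$subset[keep],
                         levels = c("lurp_only", "double_positive",
                                    "mpeg_only")))
  p <- as.numeric(counts) / n
  stats::setNames(p, names(counts))
}

#' Two-group rank comparison
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison, the convention
#' for unpaired cohort contrasts of speeds, activation times and NLA. Uses
#' the exact null distribution for small untied samples and the normal
#' approximation with tie correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (each n >= 3).
#' @return List: `p_value`, `statistic` (U for group a), `median_a`,
#'   `median_b`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 finite values")
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       median_a = stats::median(values_a), median_b = stats::median(values_b),
       n_a = length(values_a), n_b = length(values_b))
}
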