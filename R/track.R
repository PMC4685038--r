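#' Equivalent body diameter of detections
#'
#' The "body size" used by the jump criterion: the diameter of a disc with
#' the detection's whole-cell area, `2 * sqrt(WCA / pi)`. Robust to
#' frame-to-frame lamellipodial flicker compared with the tip-to-tip
#' length.
#'
#' @param detections Detection data frame with `wca_um2`.
#' @return Numeric vector of diameters (um).
#' @export
body_length_equiv <- function(detections) 2 * sqrt(detections$wca_um2 / pi)

#' Link detections between two consecutive frames
#'
#' Candidate pairs are limited to displacements of at most
#' `max_jump_body_sizes` body sizes of the earlier detection (the
#' "no jump more than 2 body sizes" criterion). Matching is one-to-one:
#' by default greedy in ascending distance (ties broken by the lower cell
#' labels), deterministically; `method = "optimal"` instead maximises the
#' number of matched pairs (minimising total distance among maximal
#' matchings) by exhaustive search and is intended for small frames and
#' verification.
#'
#' @param dets_t,dets_t1 Detection data frames for frames t and t+1.
#' @param max_jump_body_sizes Gate in body sizes (default 2).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return Data frame with columns `i` (row in `dets_t`), `j` (row in
#'   `dets_t1`) and `dist` (um); zero rows when nothing links.
#' @export
link_frames <- function(dets_t, dets_t1, max_jump_body_sizes = 2,
                        method = c("greedy", "optimal")) {
  method <- match.arg(method)
  n_t <- nrow(dets_t); n_t1 <- nrow(dets_t1)
  none <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (n_t == 0 || n_t1 == 0) return(none)
  gate <- max_jump_body_sizes * body_length_equiv(dets_t)
  dx <- outer(dets_t$x_um, dets_t1$x_um, "-")
  dy <- outer(dets_t$y_um, dets_t1$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  ok <- which(d <= gate[row(d)], arr.ind = TRUE)
  if (nrow(ok) == 0) return(none)
  cand <- data.frame(i = ok[, 1], j = ok[, 2], dist = d[ok])

  if (method == "greedy") {
    cand <- cand[order(cand$dist, dets_t$cell_label[cand$i],
                       dets_t1$cell_label[cand$j]), ]
    used_i <- logical(n_t); used_j <- logical(n_t1)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
        keep[k] <- TRUE
        used_i[cand$i[k]] <- TRUE
        used_j[cand$j[k]] <- TRUE
      }
    }
    out <- cand[keep, ]
  } else {
    out <- optimal_matching(cand, n_t)
  }
  out <- out[order(out$i), ]
  rownames(out) <- NULL
  out
}

# exhaustive search over one-to-one matchings: maximise pair count, then
# minimise total distance; recursion over rows of dets_t
optimal_matching <- function(cand, n_t) {
  by_i <- split(seq_len(nrow(cand)), factor(cand$i, levels = seq_len(n_t)))
  best <- list(count = -1L, dist = Inf, rows = integer(0))
  recurse <- function(i, used_j, rows, dist) {
    if (i > n_t) {
      cnt <- length(rows)
      if (cnt > best$count || (cnt == best$count && dist < best$dist))
        best <<- list(count = cnt, dist = dist, rows = rows)
      return(invisible())
    }
    # upper bound prune: even matching every remaining i cannot beat best
    if (length(rows) + (n_t - i + 1L) < best$count) return(invisible())
    for (k in by_i[[i]]) {
      j <- cand$j[k]
      if (!used_j[j]) {
        used_j[j] <- TRUE
        recurse(i + 1L, used_j, c(rows, k), dist + cand$dist[k])
        used_j[j] <- FALSE
      }
    }
    recurse(i + 1L, used_j, rows, dist)  # leave i unmatched
  }
  recurse(1L, logical(max(c(cand$j, 0L))), integer(0), 0)
  cand[best$rows, , drop = FALSE]
}

#' Build tracks from per-frame detections
#'
#' Applies [link_frames()] sequentially over the frame sequence. Tracks obey
#' the three criteria: detections already satisfy the size range; a missed
#' detection terminates the track (continuous presence; reappearance starts
#' a new track id); every consecutive displacement is gated at
#' `max_jump_body_sizes` body sizes of the earlier detection.
#'
#' @param detections Detection data frame over all frames (column `frame`).
#' @param max_jump_body_sizes Jump gate in body sizes.
#' @param method Matching method, see [link_frames()].
#' @return The detections with a `track_id` column, ordered by
#'   `(track_id, frame)`.
#' @export
build_tracks <- function(detections, max_jump_body_sizes = 2,
                         method = "greedy") {
  if (nrow(detections) == 0) {
    detections$track_id <- integer(0)
    return(detections)
  }
  detections <- detections[order(detections$frame, detections$cell_label), ]
  rownames(detections) <- NULL
  frames <- sort(unique(detections$frame))
  idx_by_frame <- split(seq_len(nrow(detections)), detections$frame)

  track_id <- integer(nrow(detections))
  next_id <- 1L
  first <- idx_by_frame[[as.character(frames[1])]]
  track_id[first] <- seq.int(next_id, length.out = length(first))
  next_id <- next_id + length(first)

  for (fi in seq_along(frames)[-1]) {
    prev_f <- frames[fi - 1]; cur_f <- frames[fi]
    cur_idx <- idx_by_frame[[as.character(cur_f)]]
    if (cur_f == prev_f + 1) {
      prev_idx <- idx_by_frame[[as.character(prev_f)]]
      m <- link_frames(detections[prev_idx, , drop = FALSE],
                       detections[cur_idx, , drop = FALSE],
                       max_jump_body_sizes, method)
      track_id[cur_idx[m$j]] <- track_id[prev_idx[m$i]]
    }
    # a frame gap terminates every track; unmatched detections start new ones
    new <- cur_idx[track_id[cur_idx] == 0L]
    track_id[new] <- seq.int(next_id, length.out = length(new))
    next_id <- next_id + length(new)
  }
  detections$track_id <- track_id
  detections <- detections[order(detections$track_id, detections$frame), ]
  rownames(detections) <- NULL
  detections
}

#' Drop short tracks
#'
#' @param tracks Track data frame from [build_tracks()].
#' @param min_points Minimum number of points a track must span (>= 2).
#' @return The filtered track data frame, original ordering preserved.
#' @export
filter_tracks <- function(tracks, min_points) {
  stopifnot(min_points >= 2)
  if (nrow(tracks) == 0) return(tracks)
  sizes <- table(tracks$track_id)
  keep <- names(sizes)[sizes >= min_points]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-track path summary
#'
#' @param tracks Track data frame from [build_tracks()].
#' @return Data frame per `track_id`: `n_points`, `start_frame`,
#'   `end_frame`, `path_length` (um) and `net_displacement` (um).
#' @export
track_summary <- function(tracks) {
  ids <- unique(tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), ]
    steps <- if (nrow(tr) > 1)
      sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2) else numeric(0)
    data.frame(track_id = id, n_points = nrow(tr),
               start_frame = min(tr$frame), end_frame = max(tr$frame),
               path_length = sum(steps),
               net_displacement = sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                                       (tr$y_um[nrow(tr)] - tr$y_um[1])^2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
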