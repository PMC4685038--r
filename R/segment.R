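#' Dual fluorescence threshold masks
#'
#' Lamellipodia fluoresce more dimly than the cell body, so a single channel
#' thresholded at two levels separates the whole cell (low threshold
#' `t_cell`) from the cell body (high threshold `t_body`). By construction
#' the body mask is a subset of the whole-cell mask.
#'
#' @param frame_channel Numeric `H x W` intensity matrix (one channel).
#' @param t_cell Low threshold: pixels `>= t_cell` belong to the whole cell.
#' @param t_body High threshold (`> t_cell`): pixels `>= t_body` belong to
#'   the cell body.
#' @return A list with logical matrices `whole` and `body`.
#' @export
threshold_masks <- function(frame_channel, t_cell, t_body) {
  if (!is.matrix(frame_channel)) stop("frame_channel must be a matrix")
  if (t_body <= t_cell)
    stop("invalid thresholds: t_body must exceed t_cell")
  list(whole = frame_channel >= t_cell, body = frame_channel >= t_body)
}

#' Default dual thresholds from the intensity histogram
#'
#' Otsu's method on the channel histogram supplies the body threshold; the
#' cell threshold is a fixed fraction of it. Both are overridable wherever
#' thresholds are taken.
#'
#' @param frame_channel Numeric intensity matrix.
#' @param cell_fraction `t_cell = cell_fraction * t_body` (default 0.4).
#' @return Named numeric vector `c(t_cell, t_body)`.
#' @export
default_thresholds <- function(frame_channel, cell_fraction = 0.4) {
  rng <- range(frame_channel)
  if (rng[2] <= rng[1]) stop("constant image: no threshold exists")
  scaled <- (frame_channel - rng[1]) / (rng[2] - rng[1])
  t_body <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) *
    (rng[2] - rng[1]) + rng[1]
  c(t_cell = cell_fraction * t_body, t_body = t_body)
}

# pixel centres (um) of TRUE entries of a mask: x = (col - 0.5) * ps (rightward),
# y = (row - 0.5) * ps (downward)
mask_pixel_centers <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 0.5) * pixel_size,
        y = (idx[, 1] - 0.5) * pixel_size)
}

max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n <= 1) return(0)
  if (n > 3) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
    n <- nrow(pts)
  }
  max(stats::dist(pts))
}

#' Cell length as the largest end-point separation
#'
#' The length of a segmented cell is the maximum Euclidean distance between
#' the centres of any two of its pixels, i.e. the distance between its most
#' separated end points.
#'
#' @param component_mask Logical matrix of one connected component.
#' @param pixel_size Pixel size (um/px).
#' @return Length in um (0 for a single pixel).
#' @export
cell_length <- function(component_mask, pixel_size) {
  if (!any(component_mask)) stop("empty mask has no length")
  max_pairwise_distance(mask_pixel_centers(component_mask, pixel_size))
}

#' Normalized lamellipodia area
#'
#' NLA is the ratio of the whole-cell area (WCA) to the cell-body area
#' (CBA). It is 1 for a cell without lamellipodia and grows with the
#' relative lamellipodial footprint; macrophage-like cells score higher
#' than granulocyte-like cells.
#'
#' @param wca Whole-cell area (um^2).
#' @param cba Cell-body area (um^2); must be positive and not exceed `wca`.
#' @return `wca / cba` (vectorised).
#' @export
compute_nla <- function(wca, cba) {
  if (any(cba <= 0)) stop("undefined morphology: cell body area must be > 0")
  if (any(wca < cba))
    stop("mask inconsistency: whole-cell area below cell-body area")
  wca / cba
}

#' Count lamellipodial lobes of a segmented cell
#'
#' Lobes are the connected components of the whole-cell mask minus the body
#' mask whose area reaches `min_lobe_area` (suppressing pixel-scale
#' boundary slivers).
#'
#' @param whole_component,body_component Logical matrices for one cell;
#'   `body_component` must be a subset of `whole_component`.
#' @param min_lobe_area Minimum lobe area counted (um^2).
#' @param pixel_size Pixel size (um/px).
#' @return Integer lobe count.
#' @export
count_lamellipodia <- function(whole_component, body_component,
                               min_lobe_area = 5, pixel_size = 1) {
  if (any(body_component & !whole_component))
    stop("body component must be contained in the whole component")
  fringe <- whole_component & !body_component
  if (!any(fringe)) return(0L)
  lab <- EBImage::bwlabel(fringe * 1)
  sizes <- tabulate(lab[lab > 0])
  sum(sizes * pixel_size^2 >= min_lobe_area)
}

#' Detect cells from dual-threshold masks
#'
#' Connected components of the whole-cell mask are candidate cells. A
#' candidate is kept only if it contains at least one cell-body component
#' (otherwise it is debris) and its length falls within `size_limits`
#' (default 10-60 um), the cut-offs that discriminate single cells from
#' debris and aggregates. Areas are converted to um^2 via `pixel_size^2`.
#'
#' @param whole_mask,body_mask Logical matrices from [threshold_masks()].
#' @param pixel_size Pixel size (um/px).
#' @param size_limits Length limits `c(min, max)` in um.
#' @param min_lobe_area Passed to [count_lamellipodia()].
#' @param intensities Optional `H x W x C` array; per-channel mean
#'   intensities over each cell are added as `intensity_<channel>` columns.
#' @param channel_names Channel labels for the intensity columns.
#' @param frame Frame index recorded in the output.
#' @return A data frame of detections: `frame, cell_label, x_um, y_um,
#'   wca_um2, cba_um2, nla, length_um, lamellipodia` plus intensity
#'   columns. Zero rows if nothing passes the filters.
#' @export
detect_cells <- function(whole_mask, body_mask, pixel_size,
                         size_limits = c(10, 60), min_lobe_area = 5,
                         intensities = NULL, channel_names = NULL,
                         frame = NA_integer_) {
  stopifnot(identical(dim(whole_mask), dim(body_mask)), pixel_size > 0)
  empty <- data.frame(frame = integer(0), cell_label = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      wca_um2 = numeric(0), cba_um2 = numeric(0),
                      nla = numeric(0), length_um = numeric(0),
                      lamellipodia = integer(0))
  if (!is.null(intensities))
    for (ch in channel_names) empty[[paste0("intensity_", ch)]] <- numeric(0)
  if (!any(whole_mask)) return(empty)

  lab <- EBImage::bwlabel(whole_mask * 1)
  nlabs <- max(lab)
  idx_by_lab <- split(which(lab > 0), lab[lab > 0])
  nr <- nrow(whole_mask)
  body_vec <- as.vector(body_mask)

  rows <- vector("list", nlabs)
  out_label <- 0L
  for (li in seq_len(nlabs)) {
    idx <- idx_by_lab[[as.character(li)]]
    body_idx <- idx[body_vec[idx]]
    if (length(body_idx) == 0) next          # debris: no cell body inside
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    pts <- cbind(x = (cc - 0.5) * pixel_size, y = (rr - 0.5) * pixel_size)
    len <- max_pairwise_distance(pts)
    if (len < size_limits[1] || len > size_limits[2]) next

    wca <- length(idx) * pixel_size^2
    cba <- length(body_idx) * pixel_size^2
    # lobe count on the component's bounding box
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cc); c1 <- max(cc)
    wc <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    wc[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
    bc <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    brr <- ((body_idx - 1L) %% nr) + 1L
    bcc <- ((body_idx - 1L) %/% nr) + 1L
    bc[cbind(brr - r0 + 1L, bcc - c0 + 1L)] <- TRUE
    lam <- count_lamellipodia(wc, bc, min_lobe_area, pixel_size)

    out_label <- out_label + 1L
    row <- data.frame(frame = frame, cell_label = out_label,
                      x_um = mean(pts[, "x"]), y_um = mean(pts[, "y"]),
                      wca_um2 = wca, cba_um2 = cba,
                      nla = wca / cba, length_um = len,
                      lamellipodia = lam)
    if (!is.null(intensities))
      for (ci in seq_along(channel_names))
        row[[paste0("intensity_", channel_names[ci])]] <-
          mean(intensities[, , ci][idx])
    rows[[out_label]] <- row
  }
  if (out_label == 0L) return(empty)
  out <- do.call(rbind, rows[seq_len(out_label)])
  rownames(out) <- NULL
  out
}

#' Classify detections by channel positivity
#'
#' A detection is positive in a channel when its mean intensity reaches that
#' channel's threshold. With the conventional two channels (lurp-like,
#' mpeg-like) this yields `lurp_only`, `double_positive`, `mpeg_only`, or
#' `unclassified` (below threshold everywhere; excluded from proportions).
#'
#' @param detections Detection data frame with `intensity_<channel>`
#'   columns.
#' @param positivity_thresholds Named numeric vector of per-channel
#'   thresholds, names matching the channel labels, first channel the
#'   lurp-like one.
#' @return The detections with a `subset` factor column added.
#' @export
classify_channels <- function(detections,
                              positivity_thresholds = c(lurp = 20, mpeg = 20)) {
  chans <- names(positivity_thresholds)
  cols <- paste0("intensity_", chans)
  if (!all(cols %in% names(detections)))
    stop("detections lack intensity columns for: ",
         paste(setdiff(cols, names(detections)), collapse = ", "))
  if (length(chans) != 2)
    stop("classification expects exactly two channels")
  pos1 <- detections[[cols[1]]] >= positivity_thresholds[1]
  pos2 <- detections[[cols[2]]] >= positivity_thresholds[2]
  lab <- rep("unclassified", nrow(detections))
  lab[pos1 & !pos2] <- "lurp_only"
  lab[pos1 & pos2] <- "double_positive"
  lab[!pos1 & pos2] <- "mpeg_only"
  detections$subset <- factor(lab, levels = c("lurp_only", "double_positive",
                                              "mpeg_only", "unclassified"))
  detections
}

#' Cell density per labelled subset
#'
#' @param detections Classified detection data frame (see
#'   [classify_channels()]); may have zero rows.
#' @param field_area Imaged field area in mm^2.
#' @return Data frame of `subset`, `n`, `density` (cells/mm^2), including a
#'   `total` row over classified cells.
#' @export
cell_density <- function(detections, field_area) {
  if (field_area <= 0) stop("field_area must be > 0")
  subs <- c("lurp_only", "double_positive", "mpeg_only")
  n <- if (nrow(detections) > 0 && "subset" %in% names(detections))
    vapply(subs, function(s) sum(detections$subset == s), integer(1))
  else stats::setNames(integer(3), subs)
  out <- data.frame(subset = c(subs, "total"),
                    n = c(n, sum(n)))
  out$density <- out$n / field_area
  out
}

# Cauchy-Crofton boundary length (pixel units) from intersection counts with
# line grids at 0, 45, 90, 135 degrees: L = pi/8 * (n0 + n90 + (n45 + n135)/sqrt(2))
crofton_perimeter_px <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  n_h <- sum(m[, -1] != m[, -nc])                       # horizontal lines
  n_v <- sum(m[-1, ] != m[-nr, ])                       # vertical lines
  n_d1 <- sum(m[-1, -1] != m[-nr, -nc])                 # 45 degrees
  n_d2 <- sum(m[-1, -nc] != m[-nr, -1])                 # 135 degrees
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Measure wound area and perimeter
#'
#' Area is the pixel count scaled to mm^2; the perimeter uses a
#' Cauchy-Crofton boundary estimator (intersection counts with line grids
#' in four directions), which is unbiased for smooth convex shapes where
#' naive pixel-edge counting overestimates a circle by ~27%. The estimator
#' choice is recorded in the result.
#'
#' @param wound_mask Logical matrix; must contain exactly one connected
#'   component.
#' @param pixel_size Pixel size (um/px).
#' @return List of class `wound_measure`: `area_mm2`, `perimeter_um`,
#'   `estimator`.
#' @export
measure_wound <- function(wound_mask, pixel_size) {
  if (!any(wound_mask)) stop("empty wound mask")
  lab <- EBImage::bwlabel(wound_mask * 1)
  if (max(lab) != 1) stop("wound mask must be a single connected component")
  area_mm2 <- sum(wound_mask) * pixel_size^2 / 1e6
  perimeter_um <- crofton_perimeter_px(wound_mask) * pixel_size
  structure(list(area_mm2 = area_mm2, perimeter_um = perimeter_um,
                 estimator = "crofton-4"),
            class = "wound_measure")
}

#' @export
print.wound_measure <- function(x, ...) {
  cat(sprintf("wound: area %.4f mm^2, perimeter %.0f um (%s estimator)\n",
              x$area_mm2, x$perimeter_um, x$estimator))
  invisible(x)
}

#' Segment one multi-channel frame
#'
#' The detection masks are taken on the pixel-wise maximum across channels
#' (so cells visible in either channel are found once), then per-channel
#' mean intensities are measured for classification.
#'
#' @param frame_array `H x W x C` intensity array.
#' @param t_cell,t_body Dual thresholds (see [threshold_masks()]).
#' @param pixel_size Pixel size (um/px).
#' @param channel_names Channel labels.
#' @param frame Frame index recorded in the detections.
#' @param ... Passed to [detect_cells()] (`size_limits`, `min_lobe_area`).
#' @return Detection data frame.
#' @export
segment_frame <- function(frame_array, t_cell, t_body, pixel_size,
                          channel_names, frame = NA_integer_, ...) {
  comb <- frame_array[, , 1]
  for (ci in seq_len(dim(frame_array)[3])[-1])
    comb <- pmax(comb, frame_array[, , ci])
  masks <- threshold_masks(comb, t_cell, t_body)
  detect_cells(masks$whole, masks$body, pixel_size,
               intensities = frame_array, channel_names = channel_names,
               frame = frame, ...)
}

#' Segment every frame of an image sequence
#'
#' @param images An [image_sequence()].
#' @param t_cell,t_body Dual thresholds; if `NULL`, [default_thresholds()]
#'   of the first frame's channel maximum are used.
#' @param ... Passed to [segment_frame()].
#' @return Detection data frame over all frames.
#' @export
segment_sequence <- function(images, t_cell = NULL, t_body = NULL, ...) {
  stopifnot(inherits(images, "ImageSequence"))
  if (is.null(t_cell) || is.null(t_body)) {
    f1 <- images$frames[[1]]
    comb <- f1[, , 1]
    for (ci in seq_len(dim(f1)[3])[-1]) comb <- pmax(comb, f1[, , ci])
    th <- default_thresholds(comb)
    if (is.null(t_cell)) t_cell <- th["t_cell"]
    if (is.null(t_body)) t_body <- th["t_body"]
  }
  dets <- lapply(seq_along(images$frames), function(f)
    segment_frame(images$frames[[f]], t_cell, t_body, images$pixel_size,
                  images$channel_names, frame = f, ...))
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}
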