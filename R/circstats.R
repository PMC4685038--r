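#' Cartesian displacements to polar form
#'
#' Converts displacement vectors from image coordinates (x rightward, y
#' downward) to the plotting convention used for compass/rose plots:
#' 0 degrees points along +x (image right) and angles increase
#' counterclockwise in the displayed, y-up frame, so the image-frame dy is
#' negated. A wound placed straight below the field centre therefore lies
#' at 270 degrees. Zero-length vectors carry no direction and are dropped;
#' the number dropped is recorded in the `n_zero` attribute (with a
#' warning).
#'
#' @param dx,dy Numeric vectors of displacement components (um, image
#'   frame).
#' @return Data frame `dx, dy, magnitude, angle_deg` (angle in `[0, 360)`)
#'   with attribute `n_zero`.
#' @export
to_polar <- function(dx, dy) {
  stopifnot(length(dx) == length(dy))
  zero <- dx == 0 & dy == 0
  if (any(zero))
    warning(sprintf("%d zero-length displacement(s) excluded", sum(zero)))
  dx <- dx[!zero]; dy <- dy[!zero]
  out <- data.frame(dx = dx, dy = dy,
                    magnitude = sqrt(dx^2 + dy^2),
                    angle_deg = (atan2(-dy, dx) * 180 / pi) %% 360)
  attr(out, "n_zero") <- sum(zero)
  out
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of directions departs from the uniform circular
#' distribution, using the mean resultant length
#' `rbar = |sum(exp(i * theta))| / n` and `z = n * rbar^2`. The p-value is
#' the standard small-sample approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))` with `R = n * rbar`
#' (the form used by the common circular-statistics toolboxes); a
#' Monte-Carlo p-value under the uniform null is available via
#' `method = "mc"` and serves as the independent check of the
#' approximation.
#'
#' @param angles Directions in degrees.
#' @param method `"approx"` (default) or `"mc"`.
#' @param n_mc Number of Monte-Carlo draws for `method = "mc"`.
#' @return List of class `rayleigh_test`: `n`, `rbar`, `z`, `p_value`,
#'   `method`.
#' @export
rayleigh_test <- function(angles, method = c("approx", "mc"), n_mc = 10000) {
  method <- match.arg(method)
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 4) stop("Rayleigh test needs at least 4 angles")
  th <- angles * pi / 180
  rbar <- sqrt(sum(cos(th))^2 + sum(sin(th))^2) / n
  z <- n * rbar^2
  if (method == "approx") {
    R <- n * rbar
    p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
    p <- min(1, p)
  } else {
    r_null <- rayleigh_null_rbar(n, n_mc)
    p <- (1 + sum(r_null >= rbar)) / (n_mc + 1)
  }
  structure(list(n = n, rbar = rbar, z = z, p_value = p, method = method),
            class = "rayleigh_test")
}

# mean resultant lengths of n_mc uniform samples of size n (chunked to
# bound memory)
rayleigh_null_rbar <- function(n, n_mc, chunk = 200000L) {
  out <- numeric(0)
  left <- n_mc
  while (left > 0) {
    m <- min(chunk, left)
    th <- matrix(stats::runif(n * m, 0, 2 * pi), nrow = n)
    out <- c(out, sqrt(colSums(cos(th))^2 + colSums(sin(th))^2) / n)
    left <- left - m
  }
  out
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test (%s): n = %d, rbar = %.3f, z = %.2f, p = %.3g\n",
              x$method, x$n, x$rbar, x$z, x$p_value))
  invisible(x)
}

#' Circular mean direction
#'
#' @param angles Directions in degrees; the mean resultant length must be
#'   positive for the mean direction to exist.
#' @return Mean direction in degrees, in `[0, 360)`.
#' @export
circ_mean <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 1) stop("circ_mean needs at least one angle")
  th <- angles * pi / 180
  s <- sum(sin(th)); c <- sum(cos(th))
  if (sqrt(s^2 + c^2) / length(angles) < 1e-12)
    stop("undefined direction: mean resultant length is zero")
  out <- (atan2(s, c) * 180 / pi) %% 360
  if (out > 360 - 1e-9) out <- 0   # guard against 360-epsilon wraparound
  out
}

#' Smallest absolute difference between two directions
#'
#' @param a,b Angles in degrees.
#' @return Absolute angular difference in `[0, 180]`.
#' @export
angle_difference <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Rose (angular) histogram of displacement vectors
#'
#' Bins displacement directions on the 360-degree circle and records the
#' count and mean magnitude per bin, the summary displayed as a compass or
#' rose plot.
#'
#' @param vectors Data frame from [to_polar()] (columns `angle_deg`,
#'   `magnitude`), or a numeric vector of angles (unit magnitudes assumed).
#' @param bin_width Bin width in degrees; must divide 360.
#' @return List of class `rose_histogram`: `bin_edges` (degrees,
#'   `0, bw, ..., 360`), `counts`, `mean_magnitude` (NA for empty bins),
#'   `n`.
#' @export
rose_histogram <- function(vectors, bin_width = 20) {
  if (bin_width <= 0 || 360 %% bin_width != 0)
    stop("bin_width must be a positive divisor of 360")
  if (is.numeric(vectors))
    vectors <- data.frame(angle_deg = vectors %% 360, magnitude = 1)
  edges <- seq(0, 360, by = bin_width)
  bin <- findInterval(vectors$angle_deg %% 360, edges,
                      rightmost.closed = FALSE)
  bin[bin > length(edges) - 1] <- 1L  # angle exactly 360 wraps to first bin
  counts <- tabulate(bin, nbins = length(edges) - 1)
  mm <- rep(NA_real_, length(counts))
  agg <- tapply(vectors$magnitude, bin, mean)
  mm[as.integer(names(agg))] <- as.numeric(agg)
  structure(list(bin_edges = edges, counts = counts, mean_magnitude = mm,
                 n = nrow(vectors)),
            class = "rose_histogram")
}

#' @export
print.rose_histogram <- function(x, ...) {
  cat(sprintf("rose_histogram: %d vectors in %d bins of %g degrees\n",
              x$n, length(x$counts), diff(x$bin_edges[1:2])))
  invisible(x)
}

#' Plot a rose histogram
#'
#' @param x A [rose_histogram()].
#' @param fill Bar fill colour.
#' @param ... Unused.
#' @return A ggplot object (polar bar chart, 0 degrees at the right,
#'   angles counterclockwise).
#' @export
plot.rose_histogram <- function(x, fill = "steelblue", ...) {
  bw <- diff(x$bin_edges[1:2])
  df <- data.frame(mid = x$bin_edges[-length(x$bin_edges)] + bw / 2,
                   count = x$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = bw, fill = fill, colour = "grey30") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = "direction (degrees)", y = "count") +
    ggplot2::theme_minimal()
}

#' Wound bearing from the field centre
#'
#' Direction from the field centre to the wound centre in the plotting
#' convention of [to_polar()]; with the default geometry (wound below the
#' centre) this is 270 degrees.
#'
#' @param config A [simulation_config()].
#' @return Bearing in degrees.
#' @export
wound_bearing <- function(config) {
  dx <- config$wound_center[1] - config$field_width / 2
  dy <- config$wound_center[2] - config$field_height / 2
  (atan2(-dy, dx) * 180 / pi) %% 360
}
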