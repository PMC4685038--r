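#' Phenotype specification for the wound-assay simulator
#'
#' Describes one myeloid phenotype: how many cells to place, their size and
#' lamellipodial morphology, their motility (speed distribution, persistence,
#' chemotactic attraction to the wound), activation timing after wounding,
#' fluorescence channel membership, and the stalling response to an infected
#' wound.
#'
#' Built-in defaults ([granulocyte_spec()], [macrophage_spec()],
#' [mpeg_only_spec()]) are calibrated so that the measurement pipeline
#' recovers the canonical summary statistics for larval myeloid populations:
#' small fast neutrophil-like cells (~150 um^2 whole-cell area, 3-5 um/min
#' average speed, peak 20 um/min, few front-facing lamellipodia, activation
#' within ~20 min of wounding) and large slow macrophage-like cells
#' (~330 um^2, 1-2 um/min, peak 10 um/min, many radial lamellipodia,
#' activation up to an hour later), plus a small mpeg-only subpopulation
#' amounting to 5% of labelled cells.
#'
#' @param name Phenotype label.
#' @param count Number of agents of this phenotype.
#' @param body_radius_mean,body_radius_sd Cell-body disc radius (um).
#' @param lamellipodia_count_range Integer vector `c(lo, hi)`: per-frame
#'   lamellipodium count is drawn uniformly from `lo:hi`.
#' @param lamellipodium_area_mean Mean area added per lamellipodial lobe
#'   (um^2, area outside the body disc).
#' @param lobe_spread_deg Half-angle (degrees) around the heading within
#'   which lobes are placed; 180 means lobes spread over the full circle.
#' @param speed_mean,speed_sd Activated speed distribution (um/min); each
#'   frame's speed is `max(0, Normal(speed_mean, speed_sd))`.
#' @param peak_speed Hard cap on per-frame speed (um/min).
#' @param activation_delay_mean,activation_delay_sd Delay from wounding to
#'   activation (min); sampled once per cell, truncated at 0.
#' @param persistence Probability in `[0,1]` that a step keeps (a noisy copy
#'   of) the previous heading rather than reorienting toward the wound.
#' @param chemotactic_strength von Mises-like concentration (>= 0) of the
#'   wound-directed heading component; 0 gives isotropic reorientation.
#' @param lurp_positive,mpeg_positive Channel membership flags.
#' @param stall_radius Distance from the wound centre (um) within which an
#'   activated cell stalls when the wound is infected.
#' @param stall_speed_factor Multiplier in `[0,1]` applied to the speed of a
#'   stalled cell.
#'
#' @return An object of class `phenotype_spec` (a named list).
#' @seealso [simulation_config()], [run_simulation()]
#' @export
phenotype_spec <- function(name,
                           count,
                           body_radius_mean,
                           body_radius_sd,
                           lamellipodia_count_range,
                           lamellipodium_area_mean,
                           lobe_spread_deg,
                           speed_mean,
                           speed_sd,
                           peak_speed,
                           activation_delay_mean,
                           activation_delay_sd,
                           persistence,
                           chemotactic_strength,
                           lurp_positive,
                           mpeg_positive,
                           stall_radius = 250,
                           stall_speed_factor = 0.25) {
  spec <- list(
    name = as.character(name),
    count = as.integer(count),
    body_radius_mean = body_radius_mean,
    body_radius_sd = body_radius_sd,
    lamellipodia_count_range = as.integer(lamellipodia_count_range),
    lamellipodium_area_mean = lamellipodium_area_mean,
    lobe_spread_deg = lobe_spread_deg,
    speed_mean = speed_mean,
    speed_sd = speed_sd,
    peak_speed = peak_speed,
    activation_delay_mean = activation_delay_mean,
    activation_delay_sd = activation_delay_sd,
    persistence = persistence,
    chemotactic_strength = chemotactic_strength,
    lurp_positive = isTRUE(lurp_positive),
    mpeg_positive = isTRUE(mpeg_positive),
    stall_radius = stall_radius,
    stall_speed_factor = stall_speed_factor
  )
  if (spec$count < 0) stop("count must be >= 0")
  if (spec$body_radius_sd < 0 || spec$speed_sd < 0 || spec$activation_delay_sd < 0)
    stop("dispersion parameters must be >= 0")
  if (spec$speed_mean > spec$peak_speed)
    stop("speed_mean must not exceed peak_speed")
  if (spec$persistence < 0 || spec$persistence > 1)
    stop("persistence must lie in [0,1]")
  if (spec$chemotactic_strength < 0)
    stop("chemotactic_strength must be >= 0")
  if (spec$stall_speed_factor < 0 || spec$stall_speed_factor > 1)
    stop("stall_speed_factor must lie in [0,1]")
  if (length(spec$lamellipodia_count_range) != 2L ||
      spec$lamellipodia_count_range[1] > spec$lamellipodia_count_range[2] ||
      spec$lamellipodia_count_range[1] < 0)
    stop("lamellipodia_count_range must be a non-negative interval c(lo, hi)")
  structure(spec, class = "phenotype_spec")
}

#' @rdname phenotype_spec
#' @export
granulocyte_spec <- function(count = 60, speed_mean = 4, speed_sd = 1,
                             peak_speed = 20,
                             activation_delay_mean = 10,
                             activation_delay_sd = 5,
                             chemotactic_strength = 4,
                             persistence = 0.6) {
  phenotype_spec(
    name = "granulocyte", count = count,
    body_radius_mean = 5.5, body_radius_sd = 0.4,
    lamellipodia_count_range = c(1L, 3L),
    lamellipodium_area_mean = 27.5,
    lobe_spread_deg = 45,
    speed_mean = speed_mean, speed_sd = speed_sd, peak_speed = peak_speed,
    activation_delay_mean = activation_delay_mean,
    activation_delay_sd = activation_delay_sd,
    persistence = persistence,
    chemotactic_strength = chemotactic_strength,
    lurp_positive = TRUE, mpeg_positive = FALSE
  )
}

#' @rdname phenotype_spec
#' @export
macrophage_spec <- function(count = 35, speed_mean = 1.5, speed_sd = 0.5,
                            peak_speed = 10,
                            activation_delay_mean = 40,
                            activation_delay_sd = 15,
                            chemotactic_strength = 3,
                            persistence = 0.5) {
  phenotype_spec(
    name = "macrophage", count = count,
    body_radius_mean = 7, body_radius_sd = 0.5,
    lamellipodia_count_range = c(4L, 6L),
    lamellipodium_area_mean = 35,
    lobe_spread_deg = 180,
    speed_mean = speed_mean, speed_sd = speed_sd, peak_speed = peak_speed,
    activation_delay_mean = activation_delay_mean,
    activation_delay_sd = activation_delay_sd,
    persistence = persistence,
    chemotactic_strength = chemotactic_strength,
    lurp_positive = TRUE, mpeg_positive = TRUE
  )
}

#' @rdname phenotype_spec
#' @export
mpeg_only_spec <- function(count = 5) {
  spec <- macrophage_spec(count = count)
  spec$name <- "mpeg_only"
  spec$lurp_positive <- FALSE
  spec
}

#' Simulation configuration for a synthetic wound assay
#'
#' Defines the field geometry, optical calibration, acquisition timing, wound
#' placement, infection status, phenotype mixture, and rendering intensities
#' of a synthetic two-channel time-lapse. Defaults follow the acquisition
#' scale of larval tail-fin assays: 2-min frame interval, 1.6 um/px, a
#' 0.3 mm-diameter punch wound placed below the field centre so that the
#' wound bearing from the field centre is 270 degrees in the plotting
#' convention, and a 1000 x 800 um field (0.8 mm^2).
#'
#' @param field_width,field_height Field size (um).
#' @param pixel_size Pixel size (um/px).
#' @param frame_interval Frame interval (min).
#' @param n_frames Number of frames; the default (31) spans one hour.
#' @param seed Integer seed; all randomness of [run_simulation()] flows
#'   from it.
#' @param wound_center Numeric `c(x, y)` in um, image coordinates (y grows
#'   downward). The default places the wound on the bottom edge of the
#'   field, matching the assay layout where the punch removes tissue at
#'   the fin margin and cells approach from the tissue side; only the
#'   in-field part of the wound disc is excluded when placing cells.
#' @param wound_radius Wound radius (um); default 150 (0.3 mm punch).
#' @param wound_onset_frame Frame at which the wound appears (1-based).
#'   `Inf` means no wound is ever made (unwounded control).
#' @param infected Logical; an infected wound stalls activated cells that
#'   come within `stall_radius` of the wound centre.
#' @param phenotypes List of [phenotype_spec()] objects.
#' @param background_noise_sd Gaussian background noise SD (intensity units).
#' @param body_intensity,lamellipodium_intensity Rendering intensities;
#'   lamellipodia must be dimmer than the cell body so the dual-threshold
#'   segmentation is meaningful.
#' @param quiescent_speed_factor Quiescent (pre-activation) speed as a
#'   fraction of the activated speed distribution.
#' @param heading_sd SD (radians) of heading noise for the persistent
#'   component of a step.
#' @param channel_names Channel labels; channel 1 collects lurp-positive,
#'   channel 2 mpeg-positive cells.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(field_width = 1000,
                              field_height = 800,
                              pixel_size = 1.6,
                              frame_interval = 2,
                              n_frames = 31,
                              seed = 1L,
                              wound_center = c(500, 800),
                              wound_radius = 150,
                              wound_onset_frame = 1,
                              infected = FALSE,
                              phenotypes = list(granulocyte_spec(),
                                                macrophage_spec(),
                                                mpeg_only_spec()),
                              background_noise_sd = 5,
                              body_intensity = 200,
                              lamellipodium_intensity = 80,
                              quiescent_speed_factor = 0.2,
                              heading_sd = 0.4,
                              channel_names = c("lurp", "mpeg")) {
  cfg <- list(
    field_width = field_width, field_height = field_height,
    pixel_size = pixel_size, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), seed = as.integer(seed),
    wound_center = as.numeric(wound_center), wound_radius = wound_radius,
    wound_onset_frame = wound_onset_frame, infected = isTRUE(infected),
    phenotypes = phenotypes,
    background_noise_sd = background_noise_sd,
    body_intensity = body_intensity,
    lamellipodium_intensity = lamellipodium_intensity,
    quiescent_speed_factor = quiescent_speed_factor,
    heading_sd = heading_sd,
    channel_names = channel_names
  )
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$n_frames < 1) stop("n_frames must be >= 1")
  if (cfg$lamellipodium_intensity >= cfg$body_intensity)
    stop("lamellipodium_intensity must be below body_intensity")
  if (cfg$background_noise_sd < 0) stop("background_noise_sd must be >= 0")
  if (cfg$wound_radius < 0) stop("wound_radius must be >= 0")
  if (cfg$wound_radius > 0) {
    wc <- cfg$wound_center
    if (wc[1] < 0 || wc[1] > field_width || wc[2] < 0 || wc[2] > field_height)
      stop("wound centre must lie inside the field")
  }
  if (!all(vapply(phenotypes, inherits, logical(1), "phenotype_spec")))
    stop("phenotypes must be a list of phenotype_spec objects")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Wound-assay simulation config\n")
  cat(sprintf("  field: %g x %g um, %g um/px, %d frames @ %g min\n",
              x$field_width, x$field_height, x$pixel_size,
              x$n_frames, x$frame_interval))
  cat(sprintf("  wound: centre (%g, %g), radius %g um, onset frame %s%s\n",
              x$wound_center[1], x$wound_center[2], x$wound_radius,
              format(x$wound_onset_frame),
              if (x$infected) " (infected)" else ""))
  for (p in x$phenotypes)
    cat(sprintf("  %-12s n=%3d  speed %g+/-%g um/min  delay %g+/-%g min\n",
                p$name, p$count, p$speed_mean, p$speed_sd,
                p$activation_delay_mean, p$activation_delay_sd))
  invisible(x)
}

# Expected whole-cell area implied by a phenotype spec (um^2):
# body disc (E[r^2] = mu^2 + sd^2) plus mean lobe count x added area per lobe.
expected_whole_area <- function(spec) {
  body <- pi * (spec$body_radius_mean^2 + spec$body_radius_sd^2)
  kbar <- mean(spec$lamellipodia_count_range[1]:spec$lamellipodia_count_range[2])
  body + kbar * spec$lamellipodium_area_mean
}

expected_body_area <- function(spec) {
  pi * (spec$body_radius_mean^2 + spec$body_radius_sd^2)
}

#' Initialise the agent population
#'
#' Places `sum(count)` agents uniformly at random over the field, excluding
#' the wound disc, with uniform headings; per-cell body radii and activation
#' delays are sampled from the phenotype distributions. All agents start in
#' the `quiescent` state.
#'
#' @param config A [simulation_config()].
#' @return A data frame with one row per agent (positions in um, image
#'   coordinates) carrying the per-agent motility parameters.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  total_area <- sum(vapply(config$phenotypes, function(p)
    p$count * expected_whole_area(p), numeric(1)))
  field_area <- config$field_width * config$field_height
  if (total_area > 0.5 * field_area)
    stop(sprintf(
      "population too dense: total expected cell area %.0f um^2 exceeds half the field area (%.0f um^2)",
      total_area, 0.5 * field_area))

  rows <- lapply(config$phenotypes, function(p) {
    n <- p$count
    if (n == 0L) return(NULL)
    data.frame(
      phenotype = rep(p$name, n),
      body_radius = pmax(1, stats::rnorm(n, p$body_radius_mean, p$body_radius_sd)),
      speed_mean = p$speed_mean, speed_sd = p$speed_sd,
      peak_speed = p$peak_speed,
      activation_delay = pmax(0, stats::rnorm(n, p$activation_delay_mean,
                                              p$activation_delay_sd)),
      persistence = p$persistence,
      chemotactic_strength = p$chemotactic_strength,
      lam_lo = p$lamellipodia_count_range[1],
      lam_hi = p$lamellipodia_count_range[2],
      lam_area = p$lamellipodium_area_mean,
      lobe_spread = p$lobe_spread_deg * pi / 180,
      lurp = p$lurp_positive, mpeg = p$mpeg_positive,
      stall_radius = p$stall_radius,
      stall_speed_factor = p$stall_speed_factor,
      stringsAsFactors = FALSE
    )
  })
  agents <- do.call(rbind, rows)
  if (is.null(agents)) {
    agents <- data.frame(phenotype = character(0), body_radius = numeric(0))
  }
  n <- nrow(agents)
  if (n > 0) {
    # rejection sampling of positions outside the wound disc
    x <- numeric(n); y <- numeric(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      x[todo] <- stats::runif(length(todo), 0, config$field_width)
      y[todo] <- stats::runif(length(todo), 0, config$field_height)
      if (config$wound_radius > 0) {
        d2 <- (x[todo] - config$wound_center[1])^2 +
          (y[todo] - config$wound_center[2])^2
        todo <- todo[d2 <= config$wound_radius^2]
      } else todo <- integer(0)
    }
    agents$cell_id <- seq_len(n)
    agents$x <- x
    agents$y <- y
    agents$heading <- stats::runif(n, 0, 2 * pi)
    agents$state <- rep("quiescent", n)
  } else {
    agents$cell_id <- integer(0); agents$x <- numeric(0); agents$y <- numeric(0)
    agents$heading <- numeric(0); agents$state <- character(0)
  }
  rownames(agents) <- NULL
  agents
}

# wrapped draw around a centre with concentration kappa (>0) approximated by
# a wrapped normal with sd = 1/sqrt(kappa); kappa = 0 gives a uniform draw
draw_heading <- function(centre, kappa) {
  n <- length(centre)
  out <- numeric(n)
  iso <- kappa == 0
  out[iso] <- stats::runif(sum(iso), 0, 2 * pi)
  if (any(!iso))
    out[!iso] <- stats::rnorm(sum(!iso), centre[!iso], 1 / sqrt(kappa[!iso]))
  out %% (2 * pi)
}

#' Advance the agent population by one frame
#'
#' Implements a biased persistent random walk. Quiescent agents take
#' isotropic steps at a reduced speed. Once the time elapsed since wounding
#' exceeds a cell's sampled activation delay it becomes `activated`: each
#' step keeps a wrapped-normal perturbation of the previous heading with
#' probability `persistence`, otherwise reorients toward the wound centre
#' with concentration `chemotactic_strength`. Per-frame speeds are
#' `max(0, Normal(speed_mean, speed_sd))`, capped at `peak_speed`. If the
#' wound is infected, activated agents within `stall_radius` of the wound
#' centre switch irreversibly to `stalled` and move at
#' `stall_speed_factor` times their drawn speed. Boundaries are reflective.
#'
#' @param agents Agent data frame from [init_population()] (or a previous
#'   call).
#' @param config The [simulation_config()].
#' @param frame_index Index (>= 2) of the frame being generated.
#' @return The updated agent data frame.
#' @export
step_agents <- function(agents, config, frame_index) {
  stopifnot(frame_index >= 1)
  n <- nrow(agents)
  if (n == 0) return(agents)
  dt <- config$frame_interval

  # activation
  if (is.finite(config$wound_onset_frame)) {
    elapsed <- dt * (frame_index - config$wound_onset_frame)
    act <- agents$state == "quiescent" & elapsed > agents$activation_delay
    agents$state[act] <- "activated"
  }

  # stalling (irreversible)
  if (config$infected && is.finite(config$wound_onset_frame) &&
      frame_index >= config$wound_onset_frame) {
    d <- sqrt((agents$x - config$wound_center[1])^2 +
              (agents$y - config$wound_center[2])^2)
    st <- agents$state %in% c("activated", "stalled") & d <= agents$stall_radius
    agents$state[st | agents$state == "stalled"] <- "stalled"
  }

  quiesc <- agents$state == "quiescent"
  moving <- !quiesc

  heading <- agents$heading
  if (any(moving)) {
    bearing <- atan2(config$wound_center[2] - agents$y[moving],
                     config$wound_center[1] - agents$x[moving])
    keep <- stats::runif(sum(moving)) < agents$persistence[moving]
    new_h <- numeric(sum(moving))
    if (any(keep))
      new_h[keep] <- stats::rnorm(sum(keep), heading[moving][keep],
                                  config$heading_sd)
    if (any(!keep))
      new_h[!keep] <- draw_heading(bearing[!keep],
                                   agents$chemotactic_strength[moving][!keep])
    heading[moving] <- new_h %% (2 * pi)
  }
  if (any(quiesc))
    heading[quiesc] <- stats::runif(sum(quiesc), 0, 2 * pi)

  qf <- config$quiescent_speed_factor
  mu <- ifelse(quiesc, qf * agents$speed_mean, agents$speed_mean)
  sd <- ifelse(quiesc, qf * agents$speed_sd, agents$speed_sd)
  speed <- pmax(0, stats::rnorm(n, mu, sd))
  speed <- pmin(speed, agents$peak_speed)
  stalled <- agents$state == "stalled"
  speed[stalled] <- speed[stalled] * agents$stall_speed_factor[stalled]

  step <- speed * dt
  x <- agents$x + step * cos(heading)
  y <- agents$y + step * sin(heading)

  # reflective boundaries (repeat in case of large steps)
  W <- config$field_width; H <- config$field_height
  refl_x <- x < 0 | x > W
  refl_y <- y < 0 | y > H
  for (i in 1:4) {
    x <- ifelse(x < 0, -x, x); x <- ifelse(x > W, 2 * W - x, x)
    y <- ifelse(y < 0, -y, y); y <- ifelse(y > H, 2 * H - y, y)
  }
  heading[refl_x] <- (pi - heading[refl_x]) %% (2 * pi)
  heading[refl_y] <- (-heading[refl_y]) %% (2 * pi)

  agents$x <- x; agents$y <- y; agents$heading <- heading
  agents
}

# area of intersection (lens) of two discs with radii R, r and centre
# distance d
disc_lens_area <- function(d, R, r) {
  if (d >= R + r) return(0)
  if (d <= abs(R - r)) return(pi * min(R, r)^2)
  a1 <- R^2 * acos((d^2 + R^2 - r^2) / (2 * d * R))
  a2 <- r^2 * acos((d^2 + r^2 - R^2) / (2 * d * r))
  a3 <- 0.5 * sqrt((-d + R + r) * (d + R - r) * (d - R + r) * (d + R + r))
  a1 + a2 - a3
}

# lobe radius whose disc, centred at body_radius + 0.7 * r from the cell
# centre, adds `target` um^2 outside the body disc
lobe_radius_for_area <- function(target, body_radius) {
  f <- function(r) {
    d <- body_radius + 0.7 * r
    pi * r^2 - disc_lens_area(d, body_radius, r) - target
  }
  stats::uniroot(f, c(1e-3, body_radius + sqrt(target / pi) + 5))$root
}

#' Render one two-channel frame from the agent state
#'
#' Each agent is drawn as a bright body disc plus dimmer lamellipodial lobe
#' discs overlapping the body rim; the lobe count is redrawn each frame from
#' the phenotype's range and lobes are placed around the heading within the
#' phenotype's angular spread (narrow, movement-directed for
#' granulocyte-like cells; full circle for macrophage-like cells). Gaussian
#' background noise is added and intensities are clamped at zero. A cell
#' appears in a channel iff its channel flag is positive; overlapping signal
#' combines by maximum.
#'
#' @param agents Agent data frame.
#' @param config The [simulation_config()].
#' @return An `H x W x C` intensity array with attribute `agent_areas`, a
#'   data frame of the per-agent body/whole areas actually drawn (um^2,
#'   analytic, pre-rasterisation).
#' @export
render_frame <- function(agents, config) {
  ps <- config$pixel_size
  H <- round(config$field_height / ps)
  W <- round(config$field_width / ps)
  nc <- length(config$channel_names)

  n <- nrow(agents)
  areas <- data.frame(cell_id = agents$cell_id,
                      body_area = pi * agents$body_radius^2,
                      whole_area = pi * agents$body_radius^2,
                      n_lobes = integer(n))
  # linear indices (within an H x W layer) of pixels whose centres fall in
  # the disc; pixel centres at ((col - 0.5) * ps, (row - 0.5) * ps)
  disc_idx <- function(cx, cy, r) {
    c0 <- max(1L, floor((cx - r) / ps + 0.5)); c1 <- min(W, ceiling((cx + r) / ps + 0.5))
    r0 <- max(1L, floor((cy - r) / ps + 0.5)); r1 <- min(H, ceiling((cy + r) / ps + 0.5))
    if (c0 > c1 || r0 > r1) return(integer(0))
    cols <- c0:c1; rows <- r0:r1
    px <- (cols - 0.5) * ps; py <- (rows - 0.5) * ps
    m <- outer((py - cy)^2, (px - cx)^2, "+") <= r^2
    ix <- (rep(cols, each = length(rows)) - 1L) * H + rep(rows, length(cols))
    ix[as.vector(m)]
  }

  lobe_px <- vector("list", nc)   # lamellipodium pixels per channel
  body_px <- vector("list", nc)   # body pixels per channel (painted last)
  if (n > 0) {
    chans <- cbind(agents$lurp, agents$mpeg)[, seq_len(nc), drop = FALSE]
    for (i in seq_len(n)) {
      rb <- agents$body_radius[i]
      k <- if (agents$lam_hi[i] > 0)
        sample(agents$lam_lo[i]:agents$lam_hi[i], 1L) else 0L
      lidx <- integer(0)
      if (k > 0) {
        rl <- lobe_radius_for_area(agents$lam_area[i], rb)
        d <- rb + 0.7 * rl
        spread <- agents$lobe_spread[i]
        base <- if (spread >= pi) {
          agents$heading[i] + 2 * pi * (seq_len(k) - 1) / k
        } else if (k == 1L) {
          agents$heading[i]
        } else {
          agents$heading[i] + seq(-spread, spread, length.out = k)
        }
        ang <- base + stats::rnorm(k, 0, 0.1)
        for (j in seq_len(k))
          lidx <- c(lidx, disc_idx(agents$x[i] + d * cos(ang[j]),
                                   agents$y[i] + d * sin(ang[j]), rl))
        areas$whole_area[i] <- areas$body_area[i] + k * agents$lam_area[i]
        areas$n_lobes[i] <- k
      }
      bidx <- disc_idx(agents$x[i], agents$y[i], rb)
      for (ch in which(chans[i, ])) {
        lobe_px[[ch]] <- c(lobe_px[[ch]], lidx)
        body_px[[ch]] <- c(body_px[[ch]], bidx)
      }
    }
  }
  img <- array(if (config$background_noise_sd > 0)
    stats::rnorm(H * W * nc, 0, config$background_noise_sd) else 0,
    dim = c(H, W, nc))
  for (ch in seq_len(nc)) {
    layer <- img[, , ch]
    layer[lobe_px[[ch]]] <- config$lamellipodium_intensity +
      if (config$background_noise_sd > 0)
        stats::rnorm(length(lobe_px[[ch]]), 0, config$background_noise_sd) else 0
    layer[body_px[[ch]]] <- config$body_intensity +
      if (config$background_noise_sd > 0)
        stats::rnorm(length(body_px[[ch]]), 0, config$background_noise_sd) else 0
    img[, , ch] <- layer
  }
  img <- pmax(img, 0)
  attr(img, "agent_areas") <- areas
  img
}

#' Run a complete simulation
#'
#' Generates trajectories for all frames, records the ground-truth table and
#' (optionally) renders the two-channel image stack. Trajectories and
#' rendering use separate seed streams derived from `config$seed`, so the
#' ground-truth table is byte-identical whether or not frames are rendered.
#'
#' @param config A [simulation_config()].
#' @param render Logical; render image frames (`TRUE`) or produce
#'   trajectories only (`FALSE`). Without rendering, the per-frame
#'   whole-cell areas in the truth table are the analytic expectation for
#'   the phenotype rather than the per-frame lobe draw.
#' @return A list of class `simulation_result` with elements `images` (an
#'   [ImageSequence] or `NULL`), `truth` (the ground-truth data frame with
#'   columns `frame, cell_id, x_um, y_um, phenotype, state, body_area_um2,
#'   whole_area_um2`), and `config`.
#' @export
run_simulation <- function(config, render = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * config$n_frames + 1L)

  set.seed(seeds[1])
  agents <- init_population(config)
  states <- vector("list", config$n_frames)
  states[[1]] <- agents
  for (f in seq_len(config$n_frames)[-1]) {
    set.seed(seeds[f])
    agents <- step_agents(agents, config, f)
    states[[f]] <- agents
  }

  truth_rows <- vector("list", config$n_frames)
  frames <- if (render) vector("list", config$n_frames) else NULL
  for (f in seq_len(config$n_frames)) {
    a <- states[[f]]
    tr <- data.frame(frame = rep(f, nrow(a)), cell_id = a$cell_id,
                     x_um = a$x, y_um = a$y, phenotype = a$phenotype,
                     state = a$state,
                     body_area_um2 = pi * a$body_radius^2,
                     whole_area_um2 = rep(NA_real_, nrow(a)),
                     stringsAsFactors = FALSE)
    set.seed(seeds[config$n_frames + f])
    if (render) {
      img <- render_frame(a, config)
      aa <- attr(img, "agent_areas")
      tr$whole_area_um2 <- aa$whole_area[match(tr$cell_id, aa$cell_id)]
      attr(img, "agent_areas") <- NULL
      frames[[f]] <- img
    } else {
      kbar <- (a$lam_lo + a$lam_hi) / 2
      tr$whole_area_um2 <- tr$body_area_um2 + kbar * a$lam_area
    }
    truth_rows[[f]] <- tr
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  images <- NULL
  if (render)
    images <- image_sequence(frames, pixel_size = config$pixel_size,
                             frame_interval = config$frame_interval,
                             channel_names = config$channel_names)
  structure(list(images = images, truth = truth, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d frames, %d cells, seed %d%s\n",
              x$config$n_frames, length(unique(x$truth$cell_id)),
              x$config$seed,
              if (is.null(x$images)) " (trajectories only)" else ""))
  invisible(x)
}
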