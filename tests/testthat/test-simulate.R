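test_that("population initialisation respects counts, wound exclusion and seed", {
  cfg <- simulation_config(seed = 5)
  set.seed(cfg$seed)
  pop <- init_population(cfg)
  expect_equal(nrow(pop), 100)
  expect_equal(sum(pop$phenotype == "mpeg_only"), 5)
  expect_equal(mean(pop$phenotype == "mpeg_only"), 0.05)
  # no agent starts inside the wound disc
  d <- sqrt((pop$x - cfg$wound_center[1])^2 + (pop$y - cfg$wound_center[2])^2)
  expect_true(all(d > cfg$wound_radius))
  expect_true(all(pop$x >= 0 & pop$x <= cfg$field_width))
  expect_true(all(pop$y >= 0 & pop$y <= cfg$field_height))
  expect_true(all(pop$state == "quiescent"))

  set.seed(cfg$seed)
  pop2 <- init_population(cfg)
  expect_identical(pop, pop2)

  empty <- simulation_config(phenotypes = list(granulocyte_spec(count = 0)))
  expect_equal(nrow(init_population(empty)), 0)

  dense <- simulation_config(field_width = 100, field_height = 100,
                             wound_center = c(50, 100), wound_radius = 20,
                             phenotypes = list(macrophage_spec(count = 100)))
  expect_error(init_population(dense), "dense")
})

test_that("phenotype and config invariants are enforced", {
  expect_error(granulocyte_spec(speed_mean = 25), "peak_speed")
  expect_error(phenotype_spec("x", 1, 5, -1, c(1, 2), 10, 45, 4, 1, 20,
                              0, 0, 0.5, 1, TRUE, FALSE), "dispersion")
  expect_error(simulation_config(lamellipodium_intensity = 250), "body_intensity")
  expect_error(simulation_config(wound_center = c(-5, 400)), "wound centre")
  expect_error(simulation_config(pixel_size = 0), "pixel_size")
})

test_that("steps respect the speed cap, field bounds and state machine", {
  cfg <- simulation_config(seed = 9, n_frames = 25)
  sim <- run_simulation(cfg, render = FALSE)
  tr <- sim$truth[order(sim$truth$cell_id, sim$truth$frame), ]
  caps <- vapply(cfg$phenotypes, function(p) p$peak_speed, numeric(1))
  names(caps) <- vapply(cfg$phenotypes, function(p) p$name, character(1))
  for (id in unique(tr$cell_id)) {
    t1 <- tr[tr$cell_id == id, ]
    step <- sqrt(diff(t1$x_um)^2 + diff(t1$y_um)^2)
    expect_lte(max(step), caps[t1$phenotype[1]] * cfg$frame_interval + 1e-9)
  }
  expect_true(all(tr$x_um >= 0 & tr$x_um <= cfg$field_width))
  expect_true(all(tr$y_um >= 0 & tr$y_um <= cfg$field_height))
  expect_setequal(unique(tr$state), c("quiescent", "activated"))
  # activation never reverts
  for (id in unique(tr$cell_id)) {
    st <- tr$state[tr$cell_id == id]
    expect_true(all(diff(st == "activated") >= 0))
  }
})

test_that("strong chemotaxis steers activated agents onto the wound bearing", {
  spec <- activated(granulocyte_spec(count = 30, chemotactic_strength = 1e6,
                                     persistence = 0))
  cfg <- single_phenotype_config(spec, seed = 2, n_frames = 2)
  set.seed(1)
  pop <- init_population(cfg)
  pop$state <- "activated"
  stepped <- step_agents(pop, cfg, frame_index = 2)
  bearing <- atan2(cfg$wound_center[2] - pop$y, cfg$wound_center[1] - pop$x)
  move_dir <- atan2(stepped$y - pop$y, stepped$x - pop$x)
  moved <- sqrt((stepped$x - pop$x)^2 + (stepped$y - pop$y)^2) > 1e-6
  dev_deg <- angle_difference(move_dir[moved] * 180 / pi,
                              bearing[moved] * 180 / pi)
  expect_lt(max(dev_deg), 5)
})

test_that("infected wounds stall agents irreversibly; factor 0 freezes them", {
  spec <- activated(macrophage_spec(count = 5))
  spec$stall_speed_factor <- 0
  spec$stall_radius <- 1e4          # whole field
  cfg <- single_phenotype_config(spec, seed = 4, n_frames = 10)
  cfg$infected <- TRUE
  sim <- run_simulation(cfg, render = FALSE)
  tr <- sim$truth
  late <- tr[tr$frame >= 3, ]
  expect_true(all(late$state == "stalled"))
  for (id in unique(tr$cell_id)) {
    pos <- tr[tr$cell_id == id & tr$frame >= 3, c("x_um", "y_um")]
    expect_true(all(abs(diff(pos$x_um)) < 1e-12))
    expect_true(all(abs(diff(pos$y_um)) < 1e-12))
  }
})

test_that("ground truth is deterministic, contiguous and seed-sensitive", {
  cfg <- simulation_config(seed = 21, n_frames = 8)
  s1 <- run_simulation(cfg, render = FALSE)
  s2 <- run_simulation(cfg, render = FALSE)
  expect_identical(s1$truth, s2$truth)
  s3 <- run_simulation(simulation_config(seed = 22, n_frames = 8),
                       render = FALSE)
  expect_false(identical(s1$truth$x_um, s3$truth$x_um))
  # one row per (frame, cell_id), frames contiguous per cell
  expect_false(any(duplicated(s1$truth[c("frame", "cell_id")])))
  for (id in unique(s1$truth$cell_id))
    expect_equal(diff(sort(s1$truth$frame[s1$truth$cell_id == id])),
                 rep(1, cfg$n_frames - 1))
  # single-frame simulation
  s4 <- run_simulation(simulation_config(seed = 1, n_frames = 1),
                       render = FALSE)
  expect_equal(nrow(s4$truth), 100)
})

test_that("rendered geometry matches ground truth", {
  # agent without lamellipodia: footprint equals the body disc within 10%
  bare <- granulocyte_spec(count = 1)
  bare$lamellipodia_count_range <- c(0L, 0L)
  cfg <- single_phenotype_config(bare, seed = 3, n_frames = 1, noise = 0)
  sim <- run_simulation(cfg)
  img <- sim$images$frames[[1]][, , 1]
  r <- sqrt(sim$truth$body_area_um2[1] / pi)
  expect_equal(sum(img >= cfg$body_intensity / 2),
               pi * r^2 / cfg$pixel_size^2,
               tolerance = 0.1)

  # mpeg-only cells leave no signal in the lurp channel
  cfg2 <- single_phenotype_config(mpeg_only_spec(count = 8), seed = 6,
                                  n_frames = 1, noise = 0)
  sim2 <- run_simulation(cfg2)
  expect_equal(max(sim2$images$frames[[1]][, , 1]), 0)
  expect_gt(max(sim2$images$frames[[1]][, , 2]), 0)

  # segmentation of a noise-free rendering: centroids within 1 px of truth
  # (cells without lobes, so the whole-cell centroid is the cell centre)
  cfg3 <- roundtrip_config(seed = 8, n_cells = 12, n_frames = 1)
  cfg3$phenotypes[[1]]$lamellipodia_count_range <- c(0L, 0L)
  sim3 <- run_simulation(cfg3)
  dets <- segment_sequence(sim3$images, t_cell = 40, t_body = 140)
  expect_equal(nrow(dets), 12)
  m <- match_to_truth(dets, sim3$truth, max_dist = 10)
  err <- sqrt((m$x_um - sim3$truth$x_um[match(m$true_cell_id, sim3$truth$cell_id)])^2 +
              (m$y_um - sim3$truth$y_um[match(m$true_cell_id, sim3$truth$cell_id)])^2)
  expect_true(all(err < cfg3$pixel_size))
  # with lamellipodia the whole-cell centroid wobbles with the lobe draw,
  # but stays within a couple of pixels of the cell centre
  sim4 <- run_simulation(roundtrip_config(seed = 8, n_cells = 12, n_frames = 1))
  dets4 <- segment_sequence(sim4$images, t_cell = 40, t_body = 140)
  m4 <- match_to_truth(dets4, sim4$truth, max_dist = 10)
  err4 <- sqrt((m4$x_um - sim4$truth$x_um[match(m4$true_cell_id, sim4$truth$cell_id)])^2 +
               (m4$y_um - sim4$truth$y_um[match(m4$true_cell_id, sim4$truth$cell_id)])^2)
  expect_lt(mean(err4), 2 * cfg3$pixel_size)
})

test_that("wound-directed populations approach the wound on average", {
  cfg <- simulation_config(seed = 12)
  sim <- run_simulation(cfg, render = FALSE)
  d <- with(sim$truth,
            tapply(sqrt((x_um - cfg$wound_center[1])^2 +
                        (y_um - cfg$wound_center[2])^2), frame, mean))
  expect_lt(d[length(d)], d[1])
  # decreasing trend across the recording, not just at the ends
  thirds <- split(d, cut(seq_along(d), 3))
  expect_true(mean(thirds[[1]]) > mean(thirds[[2]]))
  expect_true(mean(thirds[[2]]) > mean(thirds[[3]]))
})
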