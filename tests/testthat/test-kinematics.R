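test_that("point and average speeds follow the path-over-time definitions", {
  tr <- make_track(x = c(0, 3), y = c(0, 4))
  expect_equal(point_speeds(tr, 2), 2.5)          # 5 um over 2 min
  still <- make_track(x = rep(1, 5), y = rep(2, 5))
  expect_equal(point_speeds(still, 2), rep(0, 4))
  expect_error(point_speeds(still[1, ], 2), "at least 2")

  zig <- make_track(x = c(0, 3, 3, 6), y = c(0, 0, 4, 4))
  expect_equal(average_speed(zig, 2), 10 / 6)     # steps 3,4,3 over 6 min
  loop <- make_track(x = c(0, 5, 5, 0), y = c(0, 0, 5, 0))
  expect_gt(average_speed(loop, 2), 0)
  expect_equal(unname(net_displacement_vector(loop)), c(0, 0))
  # with even spacing the average equals the mean point speed
  set.seed(2)
  rnd <- make_track(x = cumsum(rnorm(12)), y = cumsum(rnorm(12)))
  expect_equal(average_speed(rnd, 2), mean(point_speeds(rnd, 2)))
})

test_that("net displacement is bounded by path length", {
  tr <- make_track(x = c(0, 2, 6), y = c(0, -4, -8))
  nd <- net_displacement_vector(tr)
  expect_equal(unname(nd), c(6, -8))
  expect_equal(sqrt(sum(nd^2)), 10)
  cfg <- simulation_config(seed = 27, n_frames = 15)
  sim <- run_simulation(cfg, render = FALSE)
  kin <- track_kinematics(
    build_tracks(leukotrax:::truth_detections(sim$truth, cfg)), 2)
  expect_true(all(kin$net_displacement <= kin$path_length + 1e-9))
  expect_true(all(kin$peak_speed >= 0 & kin$average_speed >= 0))
})

test_that("kinematics are invariant under rigid motions of the field", {
  set.seed(5)
  tr <- make_track(x = cumsum(runif(10, -3, 5)), y = cumsum(runif(10, -4, 4)))
  th <- 0.7
  rot <- make_track(x = 100 + cos(th) * tr$x_um - sin(th) * tr$y_um,
                    y = -40 + sin(th) * tr$x_um + cos(th) * tr$y_um)
  expect_equal(point_speeds(rot, 2), point_speeds(tr, 2))
  expect_equal(average_speed(rot, 2), average_speed(tr, 2))
  expect_equal(sqrt(sum(net_displacement_vector(rot)^2)),
               sqrt(sum(net_displacement_vector(tr)^2)))
})

test_that("activation time fires on sustained displacement above one body size", {
  # stationary 10 frames, then 4 um/frame: windows of 3 frames reach 12 um
  mv <- make_track(x = c(rep(0, 10), 4 * (1:10)), y = rep(0, 20))
  t_act <- activation_time(mv, body_length = 10, wound_time = 0,
                           frame_interval = 2, window_frames = 3)
  expect_equal(t_act, 18)   # onset at frame 10, (10 - 1) * 2 min
  # 3 um/frame never exceeds 10 um over a 3-frame window: no activation
  slow <- make_track(x = c(rep(0, 10), 3 * (1:10)), y = rep(0, 20))
  expect_true(is.na(activation_time(slow, 10, 0, 2, 3)))
  still <- make_track(x = rep(0, 20), y = rep(0, 20))
  expect_true(is.na(activation_time(still, 10, 0, 2, 3)))
})

test_that("subset proportions renormalise over classified cells", {
  dets <- data.frame(subset = factor(
    c(rep("lurp_only", 60), rep("double_positive", 35), rep("mpeg_only", 5),
      rep("unclassified", 7)),
    levels = c("lurp_only", "double_positive", "mpeg_only", "unclassified")))
  p <- subset_proportions(dets)
  expect_equal(unname(p), c(0.60, 0.35, 0.05))
  expect_equal(sum(p), 1)
  one <- data.frame(subset = factor(rep("mpeg_only", 4),
    levels = levels(dets$subset)))
  expect_equal(unname(subset_proportions(one)["mpeg_only"]), 1)
  none <- data.frame(subset = factor(rep("unclassified", 3),
    levels = levels(dets$subset)))
  expect_error(subset_proportions(none), "no classified")
})

test_that("rank comparison behaves at the degenerate and disjoint extremes", {
  same <- rep(c(1, 2, 3), 4)
  expect_gt(compare_groups(same, same)$p_value, 0.9)
  lo <- 1:10; hi <- 101:110
  cg <- compare_groups(lo, hi)
  expect_lt(cg$p_value, 0.001)
  # exact two-sided floor for disjoint n=10/10 samples: 2 / choose(20,10)
  expect_equal(cg$p_value, 2 / choose(20, 10))
  expect_equal(cg$median_a, 5.5)
  expect_error(compare_groups(1:2, 1:10), "at least 3")
})

test_that("simulated cohorts reproduce the phenotype orderings", {
  # speeds: granulocytes faster than macrophages
  g_cfg <- single_phenotype_config(activated(granulocyte_spec(count = 30)),
                                   seed = 41, n_frames = 31)
  m_cfg <- single_phenotype_config(activated(macrophage_spec(count = 30)),
                                   seed = 42, n_frames = 31)
  g_kin <- run_pipeline(g_cfg, render = FALSE)$kinematics
  m_kin <- run_pipeline(m_cfg, render = FALSE)$kinematics
  expect_gte(nrow(g_kin), 30)
  cmp <- compare_groups(g_kin$average_speed, m_kin$average_speed)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$median_a, cmp$median_b)

  # activation delays: granulocyte median earlier than macrophage median
  cfg <- simulation_config(seed = 43, n_frames = 61)
  rep0 <- run_pipeline(cfg, render = FALSE)
  tracks <- match_to_truth(rep0$tracks, rep0$truth)
  act <- function(phen, body) {
    ids <- unique(tracks$track_id[tracks$true_phenotype == phen])
    vapply(ids, function(id) {
      tr <- tracks[tracks$track_id == id, ]
      activation_time(tr, body, wound_time = 0, frame_interval = 2,
                      window_frames = 10)
    }, numeric(1))
  }
  g_act <- act("granulocyte", 2 * sqrt(95 / pi))    # CBA-equivalent diameter
  m_act <- act("macrophage", 2 * sqrt(155 / pi))
  expect_lte(stats::median(g_act, na.rm = TRUE),
             stats::median(m_act, na.rm = TRUE))

  # target chasing: a stalled cell shows a high transient peak then ~zero speed
  chase <- activated(macrophage_spec(count = 1, speed_mean = 6, speed_sd = 1))
  chase$stall_speed_factor <- 0
  chase$stall_radius <- 400
  ch_cfg <- single_phenotype_config(chase, seed = 44, n_frames = 60)
  ch_cfg$infected <- TRUE
  set.seed(44)
  ag <- init_population(ch_cfg)
  ag$x <- 500; ag$y <- 150; ag$state <- "activated"  # start outside stall zone
  pos <- data.frame(frame = 1, x_um = ag$x, y_um = ag$y, state = ag$state)
  for (f in 2:60) {
    ag <- step_agents(ag, ch_cfg, f)
    pos <- rbind(pos, data.frame(frame = f, x_um = ag$x, y_um = ag$y,
                                 state = ag$state))
  }
  ps <- point_speeds(pos, 2)
  stall_at <- which(pos$state == "stalled")[1]
  expect_false(is.na(stall_at))
  expect_gt(max(ps[seq_len(stall_at - 2)]), 2)
  expect_true(all(ps[(stall_at - 1):length(ps)] < 1e-9))
  expect_lt(average_speed(pos, 2), max(ps))
})

test_that("cohort mean speed recovers the generative speed within 10%", {
  cfg <- single_phenotype_config(activated(granulocyte_spec(count = 50)),
                                 seed = 45, n_frames = 30)
  kin <- run_pipeline(cfg, render = FALSE)$kinematics
  expect_gte(nrow(kin), 50)
  expect_lt(abs(mean(kin$average_speed) - 4) / 4, 0.10)
})
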