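test_that("dual thresholds nest and reject invalid orderings", {
  img <- matrix(0, 20, 20)
  m <- threshold_masks(img, 50, 150)
  expect_false(any(m$whole))
  expect_false(any(m$body))
  expect_error(threshold_masks(img, 150, 50), "invalid thresholds")

  img[5:10, 5:10] <- 200
  img[5:10, 11:13] <- 80
  m <- threshold_masks(img, 50, 150)
  expect_true(all(m$body <= m$whole))     # body subset of whole
  expect_equal(sum(m$body), 36)
  expect_equal(sum(m$whole), 36 + 18)
})

test_that("body mask covers only the bright disc on a rendered cell", {
  bare <- granulocyte_spec(count = 1)
  cfg <- single_phenotype_config(bare, seed = 13, n_frames = 1, noise = 0)
  sim <- run_simulation(cfg)
  ch <- sim$images$frames[[1]][, , 1]
  m <- threshold_masks(ch, 50, 150)
  # pixel-count oracle: masks equal direct comparisons against the rendering
  expect_identical(m$whole, ch >= 50)
  expect_identical(m$body, ch >= 150)
  expect_equal(sum(m$body), sum(ch >= cfg$body_intensity))
  # thresholds above the maximum yield nothing downstream
  m2 <- threshold_masks(ch, 500, 600)
  dets <- detect_cells(m2$whole, m2$body, cfg$pixel_size)
  expect_equal(nrow(dets), 0)
})

test_that("detection applies the 10-60 um size cut-offs and debris rule", {
  ps <- 1
  mk <- function(len_px, with_body = TRUE) {
    whole <- matrix(FALSE, 80, 80)
    whole[40:42, 10:(10 + len_px - 1)] <- TRUE
    body <- matrix(FALSE, 80, 80)
    if (with_body) body[41, 12:14] <- TRUE
    list(whole = whole, body = body)
  }
  short <- mk(8)    # ~8 um long: below the lower cut-off
  expect_equal(nrow(detect_cells(short$whole, short$body, ps)), 0)
  long <- mk(70)    # aggregate-sized: above the upper cut-off
  expect_equal(nrow(detect_cells(long$whole, long$body, ps)), 0)
  ok <- mk(30)
  expect_equal(nrow(detect_cells(ok$whole, ok$body, ps)), 1)
  debris <- mk(30, with_body = FALSE)   # no body component inside
  expect_equal(nrow(detect_cells(debris$whole, debris$body, ps)), 0)
})

test_that("cell length is the largest end-point separation", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(cell_length(single, 1.6), 0)
  run10 <- matrix(FALSE, 5, 20); run10[3, 6:15] <- TRUE
  expect_equal(cell_length(run10, 1.5), 13.5)   # 9 inter-centre gaps
  disc <- raster_disc(10, 1)
  expect_equal(cell_length(disc, 1), 20, tolerance = sqrt(2) / 20)
  expect_error(cell_length(matrix(FALSE, 3, 3), 1), "empty")
})

test_that("NLA is the WCA/CBA ratio with guarded domain", {
  expect_equal(compute_nla(300, 300), 1)
  expect_equal(compute_nla(330, 165), 2)
  expect_error(compute_nla(100, 0), "undefined morphology")
  expect_error(compute_nla(100, 120), "mask inconsistency")
})

test_that("lamellipodia are counted as fringe components above the area floor", {
  body <- raster_disc(6, 1, pad_px = 10)
  whole <- body
  expect_equal(count_lamellipodia(whole, body, 5, 1), 0L)
  # two disjoint 3x3 lobes touching the disc
  ctr <- nrow(body) / 2
  whole[(ctr - 1):(ctr + 1), 1:ceiling(ctr - 6)] <- TRUE
  whole[1:ceiling(ctr - 6), (ctr - 1):(ctr + 1)] <- TRUE
  expect_equal(count_lamellipodia(whole, body, 5, 1), 2L)
  # below the floor they are ignored
  expect_equal(count_lamellipodia(whole, body, 200, 1), 0L)
  expect_error(count_lamellipodia(body, whole, 5, 1), "contained")
})

test_that("channel classification and densities follow the positivity rules", {
  dets <- data.frame(frame = 1, cell_label = 1:4,
                     x_um = 1:4, y_um = 1:4,
                     wca_um2 = 100, cba_um2 = 80, nla = 1.25,
                     length_um = 15, lamellipodia = 1L,
                     intensity_lurp = c(120, 120, 3, 5),
                     intensity_mpeg = c(3, 110, 110, 4))
  cl <- classify_channels(dets, c(lurp = 20, mpeg = 20))
  expect_equal(as.character(cl$subset),
               c("lurp_only", "double_positive", "mpeg_only", "unclassified"))
  dens <- cell_density(cl, field_area = 0.1)
  expect_equal(dens$density[dens$subset == "total"], 30)
  expect_equal(dens$n[dens$subset == "mpeg_only"], 1)
  expect_error(cell_density(cl, 0), "field_area")
  empty <- cl[0, ]
  expect_equal(cell_density(empty, 1)$density, rep(0, 4))
})

test_that("wound measurement matches analytic circles and squares", {
  # 0.3 mm punch: disc of radius 150 um
  disc <- raster_disc(150, 2)
  w <- measure_wound(disc, 2)
  expect_equal(w$area_mm2, pi * 0.15^2, tolerance = 0.03)
  expect_equal(w$area_mm2, 0.0707, tolerance = 0.03)
  expect_equal(w$perimeter_um, 2 * pi * 150, tolerance = 0.03)
  # the isoperimetric inequality holds (unit-consistent: um)
  expect_gte(w$perimeter_um^2, 4 * pi * w$area_mm2 * 1e6)

  sq <- matrix(FALSE, 120, 120); sq[11:110, 11:110] <- TRUE
  ws <- measure_wound(sq, 1)
  expect_equal(ws$area_mm2, 0.01)
  expect_equal(ws$perimeter_um, 400, tolerance = 0.08)  # Crofton under-reads corners

  full <- matrix(TRUE, 50, 40)
  expect_equal(measure_wound(full, 2)$area_mm2, 50 * 40 * 4 / 1e6)
  expect_error(measure_wound(matrix(FALSE, 5, 5), 1), "empty")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(measure_wound(two, 1), "single connected")
})

test_that("detection count is monotone non-increasing in the cell threshold", {
  cfg <- roundtrip_config(seed = 17, n_cells = 12, n_frames = 1)
  sim <- run_simulation(cfg)
  fr <- sim$images$frames[[1]]
  counts <- vapply(c(30, 45, 60, 75, 90, 120), function(tc)
    nrow(segment_frame(fr, tc, 150, cfg$pixel_size, cfg$channel_names)),
    numeric(1))
  expect_equal(counts[1], 12)
  expect_true(all(diff(counts) <= 0))
})

test_that("measured areas agree with ground truth within a boundary band", {
  cfg <- roundtrip_config(seed = 19, n_cells = 12, n_frames = 1)
  sim <- run_simulation(cfg)
  dets <- segment_sequence(sim$images, t_cell = 40, t_body = 140)
  m <- match_to_truth(dets, sim$truth, max_dist = 10)
  expect_true(all(!is.na(m$true_cell_id)))
  truth_w <- sim$truth$whole_area_um2[match(m$true_cell_id, sim$truth$cell_id)]
  band <- 3.5 * sqrt(truth_w) * cfg$pixel_size  # ~ perimeter x one pixel
  expect_true(all(abs(m$wca_um2 - truth_w) <= band))
  expect_true(all(m$nla >= 1))
})
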