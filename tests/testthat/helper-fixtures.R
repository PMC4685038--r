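# logical raster of a disc of radius `radius_um`, pixel centres at
# half-integer multiples of pixel_size, disc centred in the image
raster_disc <- function(radius_um, pixel_size, pad_px = 3) {
  n <- 2 * ceiling(radius_um / pixel_size) + 2 * pad_px
  ctr <- n / 2 * pixel_size
  px <- (seq_len(n) - 0.5) * pixel_size
  outer((px - ctr)^2, (px - ctr)^2, "+") <= radius_um^2
}

# one-phenotype config with every cell activated from the first frame
single_phenotype_config <- function(spec, seed, n_frames = 30,
                                    field = c(1000, 800), noise = 5) {
  simulation_config(
    field_width = field[1], field_height = field[2],
    n_frames = n_frames, seed = seed,
    wound_center = c(field[1] / 2, field[2]),
    phenotypes = list(spec),
    background_noise_sd = noise
  )
}

activated <- function(spec) {
  spec$activation_delay_mean <- 0
  spec$activation_delay_sd <- 0
  spec
}

no_chemotaxis <- function(spec) {
  spec$chemotactic_strength <- 0
  spec
}

# straight-line track data frame
make_track <- function(x, y, frames = seq_along(x), track_id = 1L) {
  data.frame(track_id = track_id, frame = frames, x_um = x, y_um = y)
}

# sparse, noise-free configuration for round-trip checks: quiescent
# macrophage-like cells (radially symmetric lamellipodia, so the whole-cell
# centroid sits on the cell centre) wandering slowly on a large field
roundtrip_config <- function(seed, n_cells = 20, n_frames = 60) {
  simulation_config(
    field_width = 2000, field_height = 1600,
    n_frames = n_frames, seed = seed,
    wound_center = c(1000, 1600), wound_radius = 100,
    wound_onset_frame = Inf,
    phenotypes = list(no_chemotaxis(macrophage_spec(count = n_cells))),
    background_noise_sd = 0
  )
}

# sparse wound-directed granulocytes for noise-free parameter recovery
recovery_config <- function(seed, n_cells = 30, n_frames = 25) {
  simulation_config(
    field_width = 2000, field_height = 1600,
    n_frames = n_frames, seed = seed,
    wound_center = c(1000, 1600),
    phenotypes = list(activated(granulocyte_spec(count = n_cells))),
    background_noise_sd = 0
  )
}

# detections whose neighbourhood holds exactly one ground-truth cell
# (excludes fused aggregates from cohort morphometrics)
unambiguous <- function(dets, truth, radius = 25) {
  keep <- logical(nrow(dets))
  for (f in unique(dets$frame)) {
    di <- which(dets$frame == f)
    tr <- truth[truth$frame == f, , drop = FALSE]
    d <- sqrt(outer(dets$x_um[di], tr$x_um, "-")^2 +
              outer(dets$y_um[di], tr$y_um, "-")^2)
    keep[di] <- rowSums(d < radius) == 1
  }
  dets[keep, , drop = FALSE]
}
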