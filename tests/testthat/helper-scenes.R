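# Shared scene builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

no_noise <- function() list(poisson = FALSE, gain = 0, read_sigma = 0,
                            offset = 0)

# one-cell movie scene; noise off by default for exact-value tests
tiny_scene <- function(seed = 1L, n_frames = 12L, noise = no_noise(),
                       offset = 0) {
  noise$offset <- offset
  config <- scene_config(
    image_shape = c(48L, 48L), pixel_size_um = 0.2, frame_interval_s = 5,
    cells = list(list(center_um = c(4.8, 4.8), radii_um = c(3.6, 3.6),
                      expression = 100)),
    psf_sigma_um = 0.2, enrichment = 10, noise = noise, rng_seed = seed)
  protocol <- activity_protocol(rep(0, n_frames), rep(1, n_frames))
  list(config = config, protocol = protocol)
}

empty_schedule <- function(protocol) {
  structure(data.frame(droplet = integer(0), cell = integer(0),
                       x_um = numeric(0), y_um = numeric(0),
                       d_um = numeric(0), persistent = logical(0),
                       frame = integer(0), time_s = numeric(0)),
            params = list(), n_frames = protocol$n_frames,
            class = c("droplet_schedule", "data.frame"))
}

manual_schedule <- function(protocol, frames, x_um, y_um, d_um, cell = 1L) {
  rows <- do.call(rbind, lapply(seq_along(frames), function(i)
    data.frame(droplet = i, cell = cell, x_um = x_um[i], y_um = y_um[i],
               d_um = d_um[i], persistent = FALSE, frame = frames[i],
               time_s = (frames[i] - 1) * 5)))
  structure(rows, params = list(), n_frames = protocol$n_frames,
            class = c("droplet_schedule", "data.frame"))
}

# high-quality confocal z-stack fixture conditions
zstack_config <- function(seed = 1L, n_z = 30L, psf = 0.2,
                          noise = list(poisson = TRUE, gain = 0.25,
                                       read_sigma = 0.5, offset = 10)) {
  scene_config(image_shape = c(64L, 64L), n_z = n_z, pixel_size_um = 0.2,
               z_step_um = 0.25,
               cells = list(list(center_um = c(6.4, 6.4),
                                 radii_um = c(5.5, 5.5), expression = 30)),
               psf_sigma_um = psf, psf_axial_factor = 1,
               noise = noise, rng_seed = seed)
}

# rasterized solid ball mask, radius in voxels
ball_mask <- function(r, margin = 3L) {
  n <- 2L * r + 2L * margin + 1L
  c0 <- (n + 1) / 2
  co <- expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n))
  array((co$z - c0)^2 + (co$y - c0)^2 + (co$x - c0)^2 <= r^2, c(n, n, n))
}

rod_mask <- function(k = 20L) {
  rod <- array(FALSE, c(7L, 7L, k + 6L))
  rod[4L, 4L, 4L:(3L + k)] <- TRUE
  rod
}
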