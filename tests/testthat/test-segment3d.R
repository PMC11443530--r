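test_that("sphericity is near 1 for balls, low for rods, scale-invariant", {
  ball <- ball_mask(10L)
  psi_ball <- sphericity(ball, c(1, 1, 1))
  expect_gte(psi_ball, 0.95)
  expect_lte(psi_ball, 1.02)

  V <- sum(ball)
  expect_lt(abs(V - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)

  rod <- rod_mask(20L)
  expect_lt(sphericity(rod, c(1, 1, 1)), 0.5)

  expect_lt(abs(sphericity(ball, c(2, 2, 2)) - psi_ball), 1e-6)
  expect_lt(abs(sphericity(rod, c(0.5, 0.5, 0.5)) -
                  sphericity(rod, c(1, 1, 1))), 1e-6)
})

test_that("sphericity handles anisotropic voxels and degenerate shapes", {
  # same physical ball digitized on a 2:1 anisotropic grid
  n <- 25L
  co <- expand.grid(z = 1:13, y = 1:n, x = 1:n)
  ball_aniso <- array(((co$z - 7) * 2)^2 + (co$y - 13)^2 + (co$x - 13)^2
                      <= 100, c(13L, n, n))
  expect_gt(sphericity(ball_aniso, c(2, 1, 1)), 0.9)

  sheet <- array(FALSE, c(5L, 6L, 1L + 6L))
  sheet[3L, 2:5, 2:5] <- TRUE            # one voxel thick in z only
  expect_error(sphericity(sheet, c(1, 1, 1)), "planar")
  expect_error(sphericity(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), "empty")
})

test_that("segmentation recovers well-separated droplets and their
           flux-based volumes", {
  cfg <- zstack_config(seed = 3)
  dr <- data.frame(x_um = c(3.5, 9.5, 3.5, 9.5, 6.4),
                   y_um = c(3.5, 3.5, 9.5, 9.5, 6.4),
                   z_um = c(3.0, 3.0, 4.5, 4.5, 3.75),
                   d_um = c(1.0, 1.2, 1.4, 1.0, 2.0))
  seg <- segment_stack(render_zstack(dr, cfg), rolling_radius_px = 10)
  expect_equal(nrow(seg$clusters), 5L)
  # the largest droplet (d = 2 um) is PSF-resolved: flux volume within 20%
  big <- seg$clusters[which.max(seg$clusters$volume_flux_um3), ]
  expect_lt(abs(big$volume_flux_um3 - pi / 6 * 8) / (pi / 6 * 8), 0.2)
  expect_gt(min(seg$clusters$sphericity), 0.9)
  # voxel-count volume includes the PSF halo, so it exceeds flux volume
  expect_true(all(seg$clusters$volume_um3 >= seg$clusters$volume_flux_um3))
})

test_that("two droplets separated by more than 4 PSF sigma give 2 clusters", {
  cfg <- zstack_config(seed = 9)
  dr <- data.frame(x_um = c(5.0, 7.8), y_um = c(6.4, 6.4),
                   z_um = c(3.75, 3.75), d_um = c(1.2, 1.2))
  # separation 2.8 um - d = 1.6 um gap >> 4 * 0.2 um
  seg <- segment_stack(render_zstack(dr, cfg), rolling_radius_px = 10)
  expect_equal(nrow(seg$clusters), 2L)
})

test_that("a condensate-free stack yields zero clusters at a sane
           threshold", {
  cfg <- zstack_config(seed = 6)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), d_um = numeric(0))
  seg <- segment_stack(render_zstack(empty, cfg), rolling_radius_px = 10,
                       threshold = 100)
  expect_equal(nrow(seg$clusters), 0L)
})

test_that("total foreground voxel volume is conserved across clusters", {
  cfg <- zstack_config(seed = 13)
  dr <- data.frame(x_um = c(4, 9), y_um = c(4, 9), z_um = c(3, 4.5),
                   d_um = c(1.2, 1.6))
  seg <- segment_stack(render_zstack(dr, cfg), rolling_radius_px = 10)
  voxvol <- 0.25 * 0.2 * 0.2
  expect_equal(sum(seg$clusters$volume_um3), sum(seg$mask) * voxvol,
               tolerance = 1e-12)
  expect_equal(sum(seg$clusters$n_voxels), sum(seg$labels > 0L))
})

test_that("segmentation is equivariant under 90-degree rotation of an
           isotropic stack", {
  cfg <- zstack_config(seed = 2, n_z = 64L, noise = no_noise())
  cfg$z_step_um <- 0.2
  dr <- data.frame(x_um = c(4, 9), y_um = c(4, 8), z_um = c(5, 8),
                   d_um = c(1.2, 1.6))
  st <- render_zstack(dr, cfg, diffuse_cells = FALSE)
  rotated <- image_stack(aperm(st$data, c(2, 3, 1)), "ZYX", 0.2,
                         z_step_um = 0.2)
  a <- segment_stack(st, rolling_radius_px = NULL)
  b <- segment_stack(rotated, rolling_radius_px = NULL)
  expect_equal(nrow(a$clusters), nrow(b$clusters))
  expect_equal(sort(a$clusters$volume_um3), sort(b$clusters$volume_um3))
})

test_that("segment_stack insists on z calibration", {
  mov <- image_stack(array(runif(4 * 8 * 8), c(4, 8, 8)), "TYX", 0.2,
                     frame_interval_s = 5)
  expect_error(segment_stack(mov), "ZYX|z calibration")
})

test_that("expression-morphology correlation behaves on monotone, null and
           degenerate inputs", {
  cells <- data.frame(cell = 1:10, mean_intensity = 1:10,
                      total_volume = (1:10)^2,
                      mean_sphericity = rep(0.9, 10),
                      count = 10:1)
  res <- expression_vs_morphology(cells, n_perm = 500L, seed = 4L)
  expect_equal(res$rho[res$variable == "total_volume"], 1)
  expect_equal(res$rho[res$variable == "count"], -1)
  expect_true(is.na(res$rho[res$variable == "mean_sphericity"]))
  expect_lt(res$p_value[res$variable == "total_volume"], 0.01)

  # independent draws: |rho| < 0.4 in at least 95% of seeds at n = 50
  ok <- vapply(1:40, function(s) {
    set.seed(s)
    d <- data.frame(mean_intensity = rnorm(50), vol = rnorm(50))
    abs(expression_vs_morphology(d, n_perm = 50L, seed = s)$rho) < 0.4
  }, logical(1))
  expect_gte(mean(ok), 0.95)

  expect_error(expression_vs_morphology(cells[1:2, ]), "3 cells")
})

test_that("permutation p-values are reproducible and leave the RNG state
           alone", {
  cells <- data.frame(mean_intensity = rnorm(12), vol = rnorm(12))
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- expression_vs_morphology(cells, n_perm = 200L, seed = 7L)
  after <- runif(1)
  b <- expression_vs_morphology(cells, n_perm = 200L, seed = 7L)
  expect_identical(a$p_value, b$p_value)
  expect_identical(before, after)
})
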