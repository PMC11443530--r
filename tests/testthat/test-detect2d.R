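test_that("maxima counting handles flat frames, single blobs and plateaus", {
  p <- maxima_params(3)
  expect_equal(find_maxima_count(matrix(7, 10, 10), p), 0L)

  yy <- matrix(seq_len(21), 21, 21); xx <- t(yy)
  blob <- 100 * exp(-((yy - 11)^2 + (xx - 11)^2) / 8)
  expect_equal(find_maxima_count(blob, p), 1L)

  fr <- matrix(0, 6, 6); fr[2:3, 2:3] <- 9          # plateau counts once
  res <- find_maxima(fr, p)
  expect_equal(res$count, 1L)
  expect_equal(c(res$maxima$y, res$maxima$x), c(2.5, 2.5))

  expect_error(find_maxima(array(0, c(2, 2, 2)), p), "2D")
  expect_error(maxima_params(0), "prominence")
})

test_that("maxima counting matches the brute-force prominence oracle", {
  set.seed(101)
  for (i in 1:200) {
    fr <- matrix(sample(0:9, 64, replace = TRUE), 8, 8)
    prom <- sample(1:5, 1)
    thr <- sample(0:4, 1)
    expect_equal(find_maxima_count(fr, maxima_params(prom, thr)),
                 oracle_count_maxima(fr, prom, thr),
                 info = sprintf("case %d prom %d thr %d", i, prom, thr))
  }
})

test_that("maxima counting is shift-invariant and scale-equivariant", {
  set.seed(5)
  fr <- matrix(rpois(144, 20), 12, 12)
  base <- find_maxima_count(fr, maxima_params(4, 10))
  expect_equal(find_maxima_count(fr + 37, maxima_params(4, 47)), base)
  expect_equal(find_maxima_count(fr * 2.5, maxima_params(10, 25)), base)
})

test_that("edge exclusion drops maxima whose plateau touches the border", {
  fr <- matrix(0, 8, 8)
  fr[1, 4] <- 10                      # on the border
  fr[5, 5] <- 8                       # interior
  expect_equal(find_maxima_count(fr, maxima_params(2)), 2L)
  expect_equal(find_maxima_count(fr, maxima_params(2, exclude_edges = TRUE)),
               1L)
})

test_that("max-entropy threshold separates well-spaced populations", {
  x <- c(rep(10, 900), rep(200, 100))
  thr <- max_entropy_threshold(x)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_equal(max_entropy_threshold(x + 7), thr + 7)   # shift equivariance
  expect_error(max_entropy_threshold(rep(4, 50)), "constant")
})

test_that("max-entropy threshold matches the exhaustive Kapur scan", {
  set.seed(33)
  for (i in 1:150) {
    h <- random_histogram(lo = sample(0:40, 1))
    d <- histogram_data(h)
    if (length(unique(d)) < 2L) next
    lv <- min(d):max(d)
    ct <- tabulate(d - min(d) + 1L, nbins = length(lv))
    expect_equal(max_entropy_threshold(d), oracle_max_entropy(lv, ct),
                 info = paste("histogram", i))
  }
})

test_that("triangle threshold lies in range, shifts with the data and
           matches the exhaustive geometric scan", {
  # delta peak at 10 plus uniform tail to 200
  x <- c(rep(10, 500), rep(seq(30, 200, by = 10), each = 3))
  thr <- triangle_threshold(x)
  expect_gte(thr, 10)
  expect_lte(thr, 200)
  expect_equal(triangle_threshold(x + 25), thr + 25)
  set.seed(44)
  for (i in 1:150) {
    h <- random_histogram(lo = sample(0:40, 1))
    d <- histogram_data(h)
    if (length(unique(d)) < 2L) next
    lv <- min(d):max(d)
    ct <- tabulate(d - min(d) + 1L, nbins = length(lv))
    expect_equal(triangle_threshold(d), oracle_triangle(lv, ct),
                 info = paste("histogram", i))
  }
  expect_error(triangle_threshold(rep(9, 20)), "constant|one bin")
})

test_that("particle analysis labels, filters and measures components", {
  expect_equal(nrow(analyze_particles(matrix(0, 8, 8))), 0L)

  m <- matrix(0, 16, 16)
  m[2:4, 2:4] <- 1
  m[10:12, 9:11] <- 1
  parts <- analyze_particles(m, pixel_size_um = 0.2)
  expect_equal(nrow(parts), 2L)
  expect_equal(parts$area_px, c(9L, 9L))
  expect_equal(parts$equiv_diameter_um, rep(2 * sqrt(9 * 0.04 / pi), 2))

  expect_equal(nrow(analyze_particles(m, min_area_px = 10)), 0L)
  expect_error(analyze_particles(matrix(c(0, 2), 2, 2)), "binary")
})

test_that("component labelling matches a flood-fill oracle at both
           connectivities", {
  set.seed(21)
  for (i in 1:100) {
    m <- matrix(runif(256) < 0.4, 16, 16)
    expect_equal(max(label_components(m, 8L)), oracle_component_count(m, 8L))
    expect_equal(max(label_components(m, 4L)), oracle_component_count(m, 4L))
  }
})

test_that("binary outline is the 1-pixel boundary", {
  sq <- matrix(0, 9, 9); sq[3:7, 3:7] <- 1
  expect_equal(sum(binary_outline(sq)), 16L)          # 5x5 square boundary

  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(binary_outline(single), single == 1)

  full <- matrix(1, 6, 7)
  out <- binary_outline(full)
  expect_true(all(out[c(1, 6), ]) && all(out[, c(1, 7)]))
  expect_false(any(out[2:5, 2:6]))
  expect_equal(sum(binary_outline(matrix(0, 4, 4))), 0L)
})

test_that("dual-threshold counting reduces to each raw trace at a constant
           gate and stays between them otherwise", {
  sc <- demo_scene(seed = 21, n_frames = 30L)
  sched <- do.call(simulate_droplet_kinetics,
                   c(list(sc$protocol, sc$config), sc$kinetics))
  rend <- render_movie(sched, sc$protocol, sc$config, gcamp_mode = TRUE)
  bg <- roi_rect(1:4, 1:4, c(64, 64), "background")
  corrected <- subtract_background_roi(rend$stack, bg)
  mask <- sparkquant:::cell_footprint(sc$config, 1L)
  cnt <- sc$counting
  nf <- n_frames(corrected)

  all_false <- dual_threshold_count(corrected, mask, cnt$low_thr,
                                    cnt$high_thr, cnt$prominence,
                                    rep(FALSE, nf))
  expect_equal(all_false$count_merged, all_false$count_low)
  all_true <- dual_threshold_count(corrected, mask, cnt$low_thr,
                                   cnt$high_thr, cnt$prominence,
                                   rep(TRUE, nf))
  expect_equal(all_true$count_merged, all_true$count_high)

  gate <- seq_len(nf) %in% 11:30
  mixed <- dual_threshold_count(corrected, mask, cnt$low_thr, cnt$high_thr,
                                cnt$prominence, gate)
  expect_true(all(mixed$count_merged <=
                    pmax(mixed$count_low, mixed$count_high)))
  expect_true(all(mixed$count_merged >=
                    pmin(mixed$count_low, mixed$count_high)))

  expect_error(dual_threshold_count(corrected, mask, 150, 450, 100,
                                    rep(TRUE, nf - 1L)), "length")
  expect_error(dual_threshold_count(corrected, mask, 450, 150, 100,
                                    rep(TRUE, nf)), "low_thr")
})

test_that("gated dual-threshold counts recover ground truth on a
           dual-reporter movie", {
  sc <- demo_scene(seed = 77)
  sched <- do.call(simulate_droplet_kinetics,
                   c(list(sc$protocol, sc$config), sc$kinetics))
  rend <- render_movie(sched, sc$protocol, sc$config, gcamp_mode = TRUE)
  bg <- roi_rect(1:4, 1:4, c(64, 64), "background")
  corrected <- subtract_background_roi(rend$stack, bg)
  mask <- sparkquant:::cell_footprint(sc$config, 1L)
  intens <- gcamp_intensity_trace(rend$stack, mask, background_roi = bg)
  gate <- ca_gate_from_trace(intens, 1:10, 1.5)
  cnt <- sc$counting
  dc <- dual_threshold_count(corrected, mask, cnt$low_thr, cnt$high_thr,
                             cnt$prominence, gate)
  expect_true(all(abs(dc$count_merged - rend$truth$counts$count) <= 1L))
})
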