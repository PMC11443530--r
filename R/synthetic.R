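# Synthetic fluorescence-microscopy generator with exact ground truth.
#
# The generator emulates cells expressing a phase-separation kinase-activity
# reporter: a diffuse cytosolic pool out of which bright near-spherical
# droplets condense while the kinase is active, growing, coalescing and
# (unless "persistent") dissolving again once activity ceases. In dual
# reporter (gcamp) mode all reporter-derived photons additionally scale with
# a cytosolic Ca2+ trace. Every rendered movie carries per-frame ground
# truth (droplet schedule, counts, true cell intensities), so pipeline
# estimates can be scored against exact truth.

#' Scene configuration for the synthetic generator
#'
#' @param image_shape frame size in pixels `c(ny, nx)`.
#' @param n_z number of z-slices for z-stack rendering (`NULL` for movies).
#' @param pixel_size_um lateral pixel size, um/px.
#' @param z_step_um axial step for z-stacks, um.
#' @param frame_interval_s acquisition interval, s (movies).
#' @param cells list of cells, each `list(center_um = c(x, y),
#'   radii_um = c(rx, ry), expression = <mean diffuse intensity, AU/px>)`.
#'   Elliptical footprints must lie inside the image.
#' @param psf_sigma_um Gaussian proxy for the lateral optical PSF, um.
#' @param psf_axial_factor axial PSF sigma as a multiple of the lateral one
#'   (confocal axial resolution is ~2-3x worse laterally; default 2.5).
#' @param enrichment droplet-to-cytosol reporter concentration ratio; sets
#'   droplet flux as `enrichment * expression * volume / pixel area`
#'   (bigger droplets are brighter, scaling with d^3).
#' @param noise list: `poisson` (logical, shot noise), `gain` (intensity
#'   units per photon), `read_sigma` (Gaussian read noise SD), `offset`
#'   (constant camera baseline added to every pixel).
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(64L, 64L), n_z = NULL,
                         pixel_size_um = 0.2, z_step_um = 0.4,
                         frame_interval_s = 5,
                         cells = list(list(center_um = c(6.4, 6.4),
                                           radii_um = c(5, 5),
                                           expression = 80)),
                         psf_sigma_um = 0.2, psf_axial_factor = 2.5,
                         enrichment = 10,
                         noise = list(poisson = TRUE, gain = 1,
                                      read_sigma = 2, offset = 20),
                         rng_seed = 1L) {
  stopifnot(pixel_size_um > 0, psf_sigma_um >= 0, frame_interval_s > 0,
            enrichment > 0, length(image_shape) == 2L)
  if (!is.null(n_z)) stopifnot(n_z >= 1L, z_step_um > 0)
  ext <- rev(image_shape) * pixel_size_um      # (x, y) extent in um
  for (cl in cells) {
    stopifnot(length(cl$center_um) == 2L, length(cl$radii_um) == 2L,
              all(cl$radii_um > 0), cl$expression >= 0)
    if (any(cl$center_um - cl$radii_um < 0) ||
        any(cl$center_um + cl$radii_um > ext))
      stop("cell footprint extends beyond the image bounds")
  }
  noise <- utils::modifyList(
    list(poisson = TRUE, gain = 1, read_sigma = 2, offset = 20), noise)
  structure(list(image_shape = as.integer(image_shape), n_z = n_z,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 frame_interval_s = frame_interval_s, cells = cells,
                 psf_sigma_um = psf_sigma_um,
                 psf_axial_factor = psf_axial_factor,
                 enrichment = enrichment, noise = noise,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Stimulus protocol: per-frame kinase activity and Ca2+ level
#'
#' @param kinase per-frame kinase activity `a(t)` in `[0, 1]`.
#' @param ca per-frame relative Ca2+ level `c(t)` (baseline 1); defaults to
#'   a flat 1.
#' @param windows named list of stimulus windows, each a frame-index range
#'   `c(first, last)` (labels such as "glucose-free + 2-DG", "washout").
#' @return object of class `activity_protocol`.
#' @export
activity_protocol <- function(kinase, ca = NULL, windows = list()) {
  if (is.null(ca)) ca <- rep(1, length(kinase))
  if (length(ca) != length(kinase))
    stop("kinase and ca traces must have equal length")
  if (any(!is.finite(kinase)) || any(kinase < 0) || any(kinase > 1))
    stop("kinase activity must be finite and in [0, 1]")
  if (any(!is.finite(ca)) || any(ca < 0))
    stop("ca trace must be finite and non-negative")
  structure(list(kinase = kinase, ca = ca, windows = windows,
                 n_frames = length(kinase)),
            class = "activity_protocol")
}

#' Step stimulation protocol
#'
#' Convenience builder for the canonical experiment: baseline, a
#' stimulation window in which kinase activity switches on (optionally
#' after a nucleation lag) and Ca2+ is elevated, then washout.
#'
#' @param n_frames total frames.
#' @param stim_start,stim_end stimulation window (frames, inclusive).
#' @param activity_lag_frames frames after `stim_start` before kinase
#'   activity actually rises (known ground-truth latency; default 0).
#' @param ca_high Ca2+ level during stimulation (baseline 1).
#' @return an [activity_protocol].
#' @export
step_protocol <- function(n_frames, stim_start, stim_end,
                          activity_lag_frames = 0L, ca_high = 3) {
  stopifnot(stim_start >= 1L, stim_end <= n_frames, stim_start <= stim_end)
  a <- rep(0, n_frames)
  on <- min(stim_start + activity_lag_frames, stim_end)
  a[on:stim_end] <- 1
  ca <- rep(1, n_frames)
  ca[stim_start:stim_end] <- ca_high
  activity_protocol(a, ca, windows = list(
    baseline = c(1L, stim_start - 1L),
    stimulation = c(stim_start, stim_end),
    washout = c(stim_end + 1L, n_frames)))
}

# pixel-center coordinate grids in um; x along columns, y along rows
pixel_grids <- function(config) {
  ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
  px <- config$pixel_size_um
  list(x = matrix((seq_len(nx) - 0.5) * px, ny, nx, byrow = TRUE),
       y = matrix((seq_len(ny) - 0.5) * px, ny, nx))
}

#' Logical footprint mask of one configured cell
#'
#' The elliptical pixel mask of cell `i` in a [scene_config]; the mask the
#' generator itself uses, handy as the cell ROI when quantifying simulated
#' movies.
#'
#' @param config a [scene_config].
#' @param i cell index.
#' @return logical `Y x X` matrix.
#' @export
cell_footprint <- function(config, i) {
  g <- pixel_grids(config)
  cl <- config$cells[[i]]
  ((g$x - cl$center_um[1L]) / cl$radii_um[1L])^2 +
    ((g$y - cl$center_um[2L]) / cl$radii_um[2L])^2 <= 1
}

#' Simulate droplet nucleation, growth, dissolution and coalescence
#'
#' Droplets nucleate in each cell as a Poisson process with per-frame rate
#' `nucleation_rate_per_min * a(t) * dt`, at uniform positions in the cell
#' footprint (optionally respecting a minimum pairwise separation). Live
#' droplets grow as `d <- d + growth_rate * a(t) * dt`. Non-persistent
#' droplets dissolve with per-frame probability
#' `1 - exp(-dissolve_rate * (1 - a(t)) * dt)`, i.e. at the full rate when
#' activity is zero and not at all at full activity. A fraction
#' `persistent_fraction` of droplets is marked persistent at birth and
#' never dissolves (condensate "memory" of past activity). After growth,
#' droplets of the same cell whose centres come within the sum of their
#' radii coalesce into one droplet of volume-conserving diameter at the
#' volume-weighted centre (persistent if either parent was).
#'
#' Per-frame order of events: nucleation, growth, dissolution, coalescence.
#' Deterministic given `config$rng_seed`.
#'
#' @param protocol an [activity_protocol].
#' @param config a [scene_config].
#' @param nucleation_rate_per_min nucleation rate at full activity, per
#'   cell per minute.
#' @param growth_rate_um_per_min diameter growth rate at full activity.
#' @param dissolve_rate_per_min dissolution rate at zero activity.
#' @param persistent_fraction probability a droplet never dissolves.
#' @param initial_diameter_um nucleation diameter.
#' @param min_separation_um minimum distance from existing droplets at
#'   nucleation (rejection-sampled; 0 disables).
#' @param coalesce enable coalescence (default TRUE).
#' @return a `droplet_schedule`: data.frame with one row per live droplet
#'   per frame (`droplet`, `cell`, `frame`, `time_s`, `x_um`, `y_um`,
#'   `d_um`, `persistent`), with the generator parameters attached as
#'   attributes.
#' @export
simulate_droplet_kinetics <- function(protocol, config,
                                      nucleation_rate_per_min = 2,
                                      growth_rate_um_per_min = 0.3,
                                      dissolve_rate_per_min = 2,
                                      persistent_fraction = 0,
                                      initial_diameter_um = 0.6,
                                      min_separation_um = 0,
                                      coalesce = TRUE) {
  stopifnot(inherits(protocol, "activity_protocol"),
            inherits(config, "scene_config"))
  stopifnot(nucleation_rate_per_min >= 0, growth_rate_um_per_min >= 0,
            dissolve_rate_per_min >= 0,
            persistent_fraction >= 0, persistent_fraction <= 1,
            initial_diameter_um > 0)
  dt_min <- config$frame_interval_s / 60
  n_cells <- length(config$cells)
  fp <- lapply(seq_len(n_cells), function(i) {
    m <- cell_footprint(config, i)
    if (!any(m)) stop("cell ", i, " has an empty footprint: ",
                      "droplets cannot be placed")
    which(m, arr.ind = TRUE)
  })
  px <- config$pixel_size_um

  local_seed(config$rng_seed, {
    live <- data.frame(droplet = integer(0), cell = integer(0),
                       x_um = numeric(0), y_um = numeric(0),
                       d_um = numeric(0), persistent = logical(0))
    next_id <- 1L
    rows <- vector("list", protocol$n_frames)
    for (t in seq_len(protocol$n_frames)) {
      a <- protocol$kinase[t]
      # 1. nucleation
      for (ci in seq_len(n_cells)) {
        lambda <- nucleation_rate_per_min * a * dt_min
        n_new <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
        for (k in seq_len(n_new)) {
          placed <- FALSE
          for (try in seq_len(50L)) {
            j <- sample.int(nrow(fp[[ci]]), 1L)
            xx <- (fp[[ci]][j, 2L] - stats::runif(1L)) * px
            yy <- (fp[[ci]][j, 1L] - stats::runif(1L)) * px
            if (min_separation_um > 0 && nrow(live) > 0L) {
              dmin <- min(sqrt((live$x_um - xx)^2 + (live$y_um - yy)^2))
              if (dmin < min_separation_um) next
            }
            placed <- TRUE
            break
          }
          if (!placed) next               # cell too crowded this frame
          live <- rbind(live, data.frame(
            droplet = next_id, cell = ci, x_um = xx, y_um = yy,
            d_um = initial_diameter_um,
            persistent = stats::runif(1L) < persistent_fraction))
          next_id <- next_id + 1L
        }
      }
      # 2. growth
      if (nrow(live) > 0L)
        live$d_um <- live$d_um + growth_rate_um_per_min * a * dt_min
      # 3. dissolution
      if (nrow(live) > 0L) {
        p_die <- 1 - exp(-dissolve_rate_per_min * (1 - a) * dt_min)
        dies <- !live$persistent & stats::runif(nrow(live)) < p_die
        live <- live[!dies, , drop = FALSE]
      }
      # 4. coalescence (iterate until no overlapping pair remains)
      if (coalesce && nrow(live) > 1L) {
        repeat {
          merged <- FALSE
          nl <- nrow(live)
          for (i in seq_len(nl - 1L)) {
            for (j in seq(i + 1L, nl)) {
              if (live$cell[i] != live$cell[j]) next
              dist <- sqrt((live$x_um[i] - live$x_um[j])^2 +
                           (live$y_um[i] - live$y_um[j])^2)
              if (dist < (live$d_um[i] + live$d_um[j]) / 2) {
                v1 <- live$d_um[i]^3; v2 <- live$d_um[j]^3
                live$x_um[i] <- (v1 * live$x_um[i] + v2 * live$x_um[j]) /
                  (v1 + v2)
                live$y_um[i] <- (v1 * live$y_um[i] + v2 * live$y_um[j]) /
                  (v1 + v2)
                live$d_um[i] <- (v1 + v2)^(1 / 3)
                live$persistent[i] <- live$persistent[i] || live$persistent[j]
                live <- live[-j, , drop = FALSE]
                merged <- TRUE
                break
              }
            }
            if (merged) break
          }
          if (!merged) break
        }
      }
      rows[[t]] <- if (nrow(live) > 0L)
        cbind(live[, c("droplet", "cell", "x_um", "y_um", "d_um",
                       "persistent")],
              frame = t, time_s = (t - 1L) * config$frame_interval_s)
      else NULL
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(droplet = integer(0), cell = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        d_um = numeric(0), persistent = logical(0),
                        frame = integer(0), time_s = numeric(0))
    rownames(out) <- NULL
    structure(out,
              params = list(nucleation_rate_per_min = nucleation_rate_per_min,
                            growth_rate_um_per_min = growth_rate_um_per_min,
                            dissolve_rate_per_min = dissolve_rate_per_min,
                            persistent_fraction = persistent_fraction,
                            initial_diameter_um = initial_diameter_um,
                            min_separation_um = min_separation_um,
                            coalesce = coalesce),
              n_frames = protocol$n_frames,
              class = c("droplet_schedule", "data.frame"))
  })
}

# Droplet radial profile: a solid disk/ball of radius R (condensates have a
# fixed internal concentration, so they image as flat-topped spots) with a
# PSF-blurred edge. pnorm((R - r) / sigma) is the exact profile of a
# Gaussian-convolved half-space edge and an excellent approximation of the
# convolved ball for R >~ sigma; its half-maximum crossing sits at r = R, so
# the rendered spot's full width at half maximum equals the droplet
# diameter.
droplet_profile <- function(r_um, R_um, sigma_um) {
  stats::pnorm((R_um - r_um) / max(sigma_um, 1e-6))
}

# photon flux of one droplet (total blob integral, intensity units):
# enrichment x diffuse concentration x droplet volume, per unit pixel area
droplet_flux <- function(d_um, expression, config) {
  config$enrichment * expression * (pi / 6) * d_um^3 / config$pixel_size_um^2
}

apply_noise <- function(img, noise) {
  if (isTRUE(noise$poisson) && noise$gain > 0)
    img[] <- stats::rpois(length(img), pmax(img, 0) / noise$gain) * noise$gain
  if (noise$read_sigma > 0)
    img <- img + stats::rnorm(length(img), 0, noise$read_sigma)
  pmax(img, 0)
}

#' Render a time-lapse movie from a droplet schedule
#'
#' Each noise-free frame is the camera offset plus, per cell, a diffuse
#' cytosolic component and one flat-topped PSF-blurred spot per droplet
#' (see `droplet_profile`: condensates image as disks of roughly uniform
#' brightness whose full width at half maximum equals the droplet
#' diameter, with flux growing as d^3). Photon flux is
#' conserved before noise: every cell has a reporter budget
#' `expression x footprint pixels` (scaled by the Ca2+ trace in gcamp
#' mode), droplet fluxes are drawn out of that budget, and the diffuse
#' level is what remains -- so forming droplets visibly dims the cytosol,
#' and the total within-frame reporter signal per cell equals the budget
#' exactly. Blobs are normalized discretely (the rendered blob sums exactly
#' to its flux). Poisson shot noise, then Gaussian read noise, are applied
#' last. Deterministic given `config$rng_seed`.
#'
#' @param schedule a `droplet_schedule` from [simulate_droplet_kinetics].
#' @param protocol the matching [activity_protocol].
#' @param config the [scene_config].
#' @param gcamp_mode if `TRUE`, all reporter-derived intensity (diffuse and
#'   droplet) is multiplied by the per-frame Ca2+ level `c(t)`.
#' @return list with `stack` (a `TYX` [image_stack]) and `truth`: `counts`
#'   (per frame x cell true droplet count), `cell_intensity` (per frame x
#'   cell diffuse level, reporter budget, Ca2+ level), `droplets` (the
#'   schedule), `config` and `protocol` echoes.
#' @export
render_movie <- function(schedule, protocol, config, gcamp_mode = FALSE) {
  stopifnot(inherits(schedule, "droplet_schedule"),
            inherits(protocol, "activity_protocol"),
            inherits(config, "scene_config"))
  if (attr(schedule, "n_frames") != protocol$n_frames)
    stop("schedule and protocol disagree on the number of frames")
  nf <- protocol$n_frames
  ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
  g <- pixel_grids(config)
  ext <- rev(config$image_shape) * config$pixel_size_um
  n_cells <- length(config$cells)
  masks <- lapply(seq_len(n_cells), function(i) cell_footprint(config, i))
  npx <- vapply(masks, sum, numeric(1))

  if (nrow(schedule) > 0L &&
      (any(schedule$x_um < 0 | schedule$x_um > ext[1L]) ||
       any(schedule$y_um < 0 | schedule$y_um > ext[2L])))
    stop("droplet centre outside the image")

  movie <- array(0, c(nf, ny, nx))
  counts <- matrix(0L, nf, n_cells)
  diffuse_tab <- matrix(0, nf, n_cells)
  budget_tab <- matrix(0, nf, n_cells)

  local_seed(config$rng_seed + 1L, {
    for (t in seq_len(nf)) {
      ca <- if (gcamp_mode) protocol$ca[t] else 1
      frame <- matrix(config$noise$offset, ny, nx)
      dr_t <- schedule[schedule$frame == t, , drop = FALSE]
      for (ci in seq_len(n_cells)) {
        expr_lvl <- config$cells[[ci]]$expression
        budget <- expr_lvl * npx[ci]
        dr <- dr_t[dr_t$cell == ci, , drop = FALSE]
        counts[t, ci] <- nrow(dr)
        flux <- if (nrow(dr) > 0L)
          droplet_flux(dr$d_um, expr_lvl, config) else numeric(0)
        total_flux <- sum(flux)
        if (total_flux > 0.9 * budget) {   # droplets cannot drain the pool
          flux <- flux * 0.9 * budget / total_flux
          total_flux <- 0.9 * budget
        }
        diffuse <- (budget - total_flux) / npx[ci]
        reporter <- matrix(0, ny, nx)
        reporter[masks[[ci]]] <- diffuse
        if (nrow(dr) > 0L) {
          for (k in seq_len(nrow(dr))) {
            r <- sqrt((g$x - dr$x_um[k])^2 + (g$y - dr$y_um[k])^2)
            blob <- droplet_profile(r, dr$d_um[k] / 2, config$psf_sigma_um)
            reporter <- reporter + flux[k] * blob / sum(blob)
          }
        }
        frame <- frame + ca * reporter
        diffuse_tab[t, ci] <- ca * diffuse
        budget_tab[t, ci] <- ca * budget
      }
      movie[t, , ] <- apply_noise(frame, config$noise)
    }
  })
  stack <- image_stack(movie, "TYX", config$pixel_size_um,
                       frame_interval_s = config$frame_interval_s)
  truth <- list(
    counts = data.frame(frame = rep(seq_len(nf), n_cells),
                        cell = rep(seq_len(n_cells), each = nf),
                        count = as.vector(counts)),
    cell_intensity = data.frame(frame = rep(seq_len(nf), n_cells),
                                cell = rep(seq_len(n_cells), each = nf),
                                diffuse_level = as.vector(diffuse_tab),
                                reporter_budget = as.vector(budget_tab),
                                ca = rep(protocol$ca, n_cells)),
    droplets = schedule, config = config, protocol = protocol,
    gcamp_mode = gcamp_mode)
  list(stack = stack, truth = truth)
}

#' Render a confocal z-stack of 3D droplets
#'
#' Droplets are rendered as solid balls with PSF-blurred edges on an
#' anisotropic voxel grid (the axial edge softness uses
#' `psf_axial_factor`); an optional diffuse ellipsoidal cell body can be
#' added. Noise as in [render_movie]. Deterministic given
#' `config$rng_seed`.
#'
#' @param droplets data.frame with `x_um`, `y_um`, `z_um`, `d_um`.
#' @param config a [scene_config] with `n_z` set.
#' @param diffuse_cells if `TRUE`, add each configured cell as a diffuse
#'   ellipsoid (z semi-axis = half the stack depth).
#' @return a `ZYX` [image_stack].
#' @export
render_zstack <- function(droplets, config, diffuse_cells = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (is.null(config$n_z) || is.null(config$z_step_um) ||
      config$z_step_um <= 0)
    stop("z-stack rendering requires n_z and a positive z_step_um")
  nz <- config$n_z; ny <- config$image_shape[1L]; nx <- config$image_shape[2L]
  g <- pixel_grids(config)
  zc <- (seq_len(nz) - 0.5) * config$z_step_um
  depth <- nz * config$z_step_um
  ext <- rev(config$image_shape) * config$pixel_size_um
  if (nrow(droplets) > 0L &&
      (any(droplets$x_um < 0 | droplets$x_um > ext[1L]) ||
       any(droplets$y_um < 0 | droplets$y_um > ext[2L]) ||
       any(droplets$z_um < 0 | droplets$z_um > depth)))
    stop("droplet centre outside the stack")

  vol <- array(config$noise$offset, c(nz, ny, nx))
  if (diffuse_cells) {
    body_vol <- array(0, c(nz, ny, nx))
    for (ci in seq_along(config$cells)) {
      cl <- config$cells[[ci]]
      rz <- depth / 2
      for (z in seq_len(nz)) {
        inz <- ((zc[z] - depth / 2) / rz)^2
        body <- ((g$x - cl$center_um[1L]) / cl$radii_um[1L])^2 +
          ((g$y - cl$center_um[2L]) / cl$radii_um[2L])^2 + inz <= 1
        sl <- matrix(0, ny, nx)
        sl[body] <- cl$expression
        body_vol[z, , ] <- body_vol[z, , ] + sl
      }
    }
    # the cytosolic pool is blurred by the optics like everything else;
    # razor-edged bodies would leave rolling-ball edge residues no real
    # acquisition shows
    sig_vox <- c(config$psf_sigma_um * config$psf_axial_factor /
                   config$z_step_um,
                 config$psf_sigma_um / config$pixel_size_um,
                 config$psf_sigma_um / config$pixel_size_um)
    vol <- vol + smooth3d(body_vol, sig_vox)
  }
  expr_ref <- config$cells[[1L]]$expression
  sxy <- config$psf_sigma_um
  sz <- config$psf_sigma_um * config$psf_axial_factor
  for (k in seq_len(nrow(droplets))) {
    flux <- config$enrichment * expr_ref * (pi / 6) * droplets$d_um[k]^3 /
      (config$pixel_size_um^2 * config$z_step_um)
    R <- droplets$d_um[k] / 2
    rho2 <- (g$x - droplets$x_um[k])^2 + (g$y - droplets$y_um[k])^2
    blob <- array(0, c(nz, ny, nx))
    for (z in seq_len(nz)) {
      dz2 <- (zc[z] - droplets$z_um[k])^2
      r2 <- rho2 + dz2
      r <- sqrt(r2)
      # PSF width along the radial direction (lateral/axial anisotropy)
      sdir <- sqrt((sxy^2 * rho2 + sz^2 * dz2) / pmax(r2, 1e-12))
      sdir[r2 < 1e-12] <- sxy
      blob[z, , ] <- droplet_profile(r, R, sdir)
    }
    vol <- vol + flux * blob / sum(blob)
  }
  local_seed(config$rng_seed + 2L, {
    vol[] <- apply_noise(vol, config$noise)
  })
  image_stack(vol, "ZYX", config$pixel_size_um,
              z_step_um = config$z_step_um)
}
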