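# 3D condensate segmentation and morphometry.
#
# The segmentation chain mirrors the published z-stack procedure: rolling-ball
# background subtraction per slice, pixel-wise self-multiplication, global
# 8-bit rescale, Triangle threshold on the whole-stack histogram, then
# 26-connected labelling and per-cluster morphometry in physical units on the
# anisotropic voxel grid.

# --- separable Gaussian smoothing of a 3D array (voxel-unit sigmas) --------
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

smooth3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    k <- gauss_kernel(sigma_vox[ax])
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    out <- array(0, d)
    for (j in seq_along(k)) {
      s <- j - r - 1L                       # shift along axis ax
      src <- pmin(pmax(seq_len(d[ax]) - s, 1L), d[ax])
      # zero-fill outside rather than clamp: mask arrays are padded upstream
      valid <- seq_len(d[ax]) - s >= 1L & seq_len(d[ax]) - s <= d[ax]
      idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx[[ax]] <- src
      contrib <- a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      zero <- which(!valid)
      if (length(zero) > 0L) {
        zi <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
        zi[[ax]] <- zero
        contrib[zi[[1]], zi[[2]], zi[[3]]] <- 0
      }
      out <- out + k[j] * contrib
    }
    a <- out
  }
  a
}

shift3d <- function(a, s, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    dst[[ax]] <- max(1L, 1L + s[ax]):min(d[ax], d[ax] + s[ax])
    src[[ax]] <- dst[[ax]] - s[ax]
    if (dst[[ax]][1L] > dst[[ax]][length(dst[[ax]])]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out
}

#' Surface area of a voxelized cluster
#'
#' Normal-corrected exposed-face projection: every exposed voxel face
#' contributes its physical face area weighted by the cosine between the
#' face normal and the local surface normal, estimated from the gradient of
#' a Gaussian-regularized indicator function evaluated at the face midpoint
#' (staggered difference along the face axis, averaged central differences
#' across it). For an axis-aligned staircase digitization of a smooth
#' surface the weighted projections tile the true surface, so the estimator
#' is asymptotically unbiased for balls and exact for axis-aligned flat
#' faces, unlike raw face counting (which overestimates a ball's area by
#' ~1.5x) or a midpoint marching-cubes mesh (which overestimates a ball by
#' ~9% and underestimates voxel-thin rods by ~30%).
#'
#' The regularization scale is `sigma_scale` times the smallest voxel
#' dimension, so the estimate is invariant under uniform scaling of the
#' voxel grid.
#'
#' @param mask logical/0-1 3D array (`Z x Y x X`) of one cluster.
#' @param dims voxel dimensions `c(dz, dy, dx)` in micrometres.
#' @param sigma_scale regularization scale in units of the smallest voxel
#'   dimension (default 1.5).
#' @return surface area in square micrometres.
#' @export
cluster_surface_area <- function(mask, dims, sigma_scale = 1.5) {
  stopifnot(length(dim(mask)) == 3L, length(dims) == 3L, all(dims > 0))
  pad <- 4L
  d0 <- dim(mask)
  m <- array(0, d0 + 2L * pad)
  m[pad + seq_len(d0[1]), pad + seq_len(d0[2]), pad + seq_len(d0[3])] <-
    as.numeric(mask != 0)
  sigma_phys <- sigma_scale * min(dims)
  sm <- smooth3d(m, sigma_phys / dims)
  d <- dim(m)
  # central-difference gradient at voxel centers, physical units
  cg <- lapply(1:3, function(ax) {
    s <- c(0L, 0L, 0L)
    s[ax] <- 1L
    (shift3d(sm, -s) - shift3d(sm, s)) / (2 * dims[ax])
  })
  mb <- m != 0
  face_area <- c(dims[2] * dims[3], dims[1] * dims[3], dims[1] * dims[2])
  A <- 0
  for (ax in 1:3) {
    s <- c(0L, 0L, 0L)
    for (sgn in c(1L, -1L)) {
      s[ax] <- sgn
      nb <- shift3d(mb, -s, fill = FALSE)   # neighbor one step +sgn along ax
      exposed <- mb & !nb
      if (!any(exposed)) next
      sm_nb <- shift3d(sm, -s)
      g_ax <- (sm_nb - sm) / (sgn * dims[ax])
      comps <- vector("list", 3L)
      for (t in 1:3) {
        if (t == ax) { comps[[t]] <- g_ax; next }
        comps[[t]] <- 0.5 * (cg[[t]] + shift3d(cg[[t]], -s))
      }
      nrm <- sqrt(comps[[1]]^2 + comps[[2]]^2 + comps[[3]]^2)
      nrm[nrm == 0] <- Inf
      dt <- sgn * (-comps[[ax]]) / nrm
      A <- A + face_area[ax] * sum(pmax(dt[exposed], 0))
    }
  }
  A
}

#' Sphericity of a voxelized cluster
#'
#' Psi = pi^(1/3) (6 V)^(2/3) / A with the volume from the voxel count and
#' the surface area from [cluster_surface_area]. Psi is 1 for a perfect
#' ball in the continuum limit and decreases for elongated or amorphous
#' shapes; discretization can push estimates slightly above 1 for very
#' small clusters (tolerance about 0.06 at the 8-voxel reliability floor).
#' Clusters below 8 voxels are computed but flagged unreliable by
#' [cluster_metrics]; sheet-like voxel sets one voxel thick in exactly one
#' dimension but extended in the other two have no meaningful enclosed
#' volume and raise an error.
#'
#' @inheritParams cluster_surface_area
#' @return sphericity, a single number in (0, ~1].
#' @export
sphericity <- function(mask, dims, sigma_scale = 1.5) {
  m <- mask != 0
  nvox <- sum(m)
  if (nvox == 0L) stop("empty cluster")
  ext <- vapply(1:3, function(ax)
    length(unique(which(m, arr.ind = TRUE)[, ax])), integer(1))
  if (sum(ext == 1L) == 1L && all(ext[ext > 1L] > 1L))
    stop("degenerate planar voxel set: sphericity undefined")
  V <- nvox * prod(dims)
  A <- cluster_surface_area(m, dims, sigma_scale)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Morphometry of labelled 3D clusters
#'
#' @param labels integer 3D label array from [label_components].
#' @param dims voxel dimensions `c(dz, dy, dx)` in micrometres.
#' @param min_voxels clusters below this voxel count are flagged
#'   `reliable = FALSE` (default 8).
#' @return data.frame with per-cluster `label`, `n_voxels`, `volume_um3`,
#'   `surface_um2`, `sphericity`, `equiv_diameter_um` (= (6V/pi)^(1/3)),
#'   centroid (`z_um`, `y_um`, `x_um`) and `reliable`.
#' @export
cluster_metrics <- function(labels, dims, min_voxels = 8L) {
  nlab <- max(labels)
  voxvol <- prod(dims)
  rows <- vector("list", nlab)
  dm <- dim(labels)
  for (l in seq_len(nlab)) {
    idx <- which(labels == l)
    co <- arrayInd(idx, dm)
    bb_lo <- apply(co, 2L, min); bb_hi <- apply(co, 2L, max)
    sub <- array(FALSE, bb_hi - bb_lo + 1L)
    sub[cbind(co[, 1] - bb_lo[1] + 1L, co[, 2] - bb_lo[2] + 1L,
              co[, 3] - bb_lo[3] + 1L)] <- TRUE
    V <- length(idx) * voxvol
    A <- cluster_surface_area(sub, dims)
    psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
    rows[[l]] <- data.frame(
      label = l, n_voxels = length(idx), volume_um3 = V, surface_um2 = A,
      sphericity = psi,
      equiv_diameter_um = (6 * V / pi)^(1 / 3),
      z_um = (mean(co[, 1]) - 0.5) * dims[1],
      y_um = (mean(co[, 2]) - 0.5) * dims[2],
      x_um = (mean(co[, 3]) - 0.5) * dims[3],
      reliable = length(idx) >= min_voxels)
  }
  if (nlab == 0L)
    return(data.frame(label = integer(0), n_voxels = integer(0),
                      volume_um3 = numeric(0), surface_um2 = numeric(0),
                      sphericity = numeric(0), equiv_diameter_um = numeric(0),
                      z_um = numeric(0), y_um = numeric(0), x_um = numeric(0),
                      reliable = logical(0)))
  do.call(rbind, rows)
}

#' Segment condensates in a calibrated z-stack
#'
#' Applies the published conditioning chain in order -- per-slice
#' rolling-ball background subtraction, pixel-wise self-multiplication,
#' 8-bit rescale using the global stack minimum/maximum (one mapping, one
#' histogram) -- then a Triangle threshold on the whole-stack intensity
#' histogram, 26-connected 3D labelling, and per-cluster morphometry with
#' anisotropic voxel dimensions.
#'
#' @param stack a `ZYX` [image_stack] with z calibration.
#' @param rolling_radius_px rolling-ball radius in pixels; `NULL` skips the
#'   background step (for already background-free stacks).
#' @param connectivity 3D connectivity (default 26).
#' @param min_voxels reliability floor passed to [cluster_metrics]; clusters
#'   of fewer voxels than `min_keep` are discarded as shot noise.
#' @param min_keep minimum cluster size in voxels kept at all (default 2).
#' @param min_peak_snr clusters whose brightest (pre-squaring) voxel is less
#'   than this many robust noise SDs above the background median are
#'   discarded as shot noise (default 10; across the ~10^5 voxels of a
#'   typical stack, noise extremes reach 6-7 robust SDs while condensates
#'   at ~10x enrichment sit far higher).
#' @param threshold optional absolute threshold on the 8-bit scale,
#'   bypassing the Triangle method. Histogram auto-thresholds presuppose
#'   that a foreground population exists; on an object-free stack they cut
#'   into the noise tail, so condensate-free stacks should be segmented
#'   with an explicit sane threshold (anything above the noise band yields
#'   zero clusters).
#' Two volume readouts are reported per cluster. `volume_um3` is the voxel
#' count times the voxel volume (it sums exactly to the segmented
#' foreground volume), but for PSF-sized objects it systematically includes
#' the blur halo down to the threshold level. `volume_flux_um3` divides the
#' cluster's integrated (pre-squaring, background-subtracted) intensity by
#' its plateau intensity (mean of the top 5% of cluster voxels):
#' convolution with the PSF conserves flux, so this estimate is insensitive
#' to where the threshold cuts the halo and recovers the physical droplet
#' volume.
#'
#' @return list with `clusters` (the [cluster_metrics] data.frame plus
#'   `volume_flux_um3`), `labels` (the label array), `threshold` (Triangle
#'   threshold on the 8-bit scale) and `mask`.
#' @export
segment_stack <- function(stack, rolling_radius_px = 10,
                          connectivity = 26L, min_voxels = 8L,
                          min_keep = 2L, min_peak_snr = 10,
                          threshold = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axes != "ZYX" || is.null(stack$z_step_um))
    stop("segment_stack requires a ZYX stack with z calibration")
  s <- stack
  if (!is.null(rolling_radius_px))
    s <- rolling_ball_subtract(s, rolling_radius_px)
  pre <- s                                # pre-squaring intensities
  s <- self_multiply(s)
  s <- rescale_to_8bit(s)                 # global stack min/max
  thr <- if (is.null(threshold)) triangle_threshold(s) else threshold
  mask <- s$data > thr
  labels <- label_components(mask, connectivity)
  if (max(labels) > 0L) {
    nlab <- max(labels)
    sizes <- tabulate(labels[labels > 0L], nbins = nlab)
    bg_med <- stats::median(pre$data)
    noise_sd <- stats::mad(pre$data)
    peaks <- vapply(seq_len(nlab), function(l) max(pre$data[labels == l]),
                    numeric(1))
    keep <- which(sizes >= min_keep &
                    (noise_sd == 0 |
                       peaks >= bg_med + min_peak_snr * noise_sd))
    if (length(keep) < nlab) {
      # relabel compactly, preserving raster order (index 1 = background)
      remap <- integer(nlab + 1L)
      remap[keep + 1L] <- seq_along(keep)
      labels[] <- remap[labels + 1L]
    }
  }
  dims <- c(stack$z_step_um, stack$pixel_size_um, stack$pixel_size_um)
  clusters <- cluster_metrics(labels, dims, min_voxels)
  voxvol <- prod(dims)
  clusters$volume_flux_um3 <- vapply(clusters$label, function(l) {
    I <- pre$data[labels == l]
    plateau <- mean(I[I >= stats::quantile(I, 0.95)])
    if (plateau <= 0) return(NA_real_)
    sum(I) / plateau * voxvol
  }, numeric(1))
  list(clusters = clusters, labels = labels, threshold = thr,
       mask = labels > 0L)
}

#' Expression level versus condensate morphology
#'
#' Spearman rank correlation of per-cell mean fluorescence intensity (an
#' expression proxy) against each condensate summary (cluster count, total
#' volume, mean volume, mean sphericity), with a two-sided permutation
#' p-value. Ranks are used because absolute intensity scales vary between
#' acquisitions; the permutation test avoids distributional assumptions at
#' the small cell counts typical of z-stack experiments.
#'
#' @param cells data.frame with column `mean_intensity` plus one column per
#'   morphology summary (any numeric columns besides `cell` and
#'   `mean_intensity` are used).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation test.
#' @return data.frame with `variable`, `rho`, `p_value`, `n`; `rho` is `NA`
#'   (with `note`) for constant covariates.
#' @export
expression_vs_morphology <- function(cells, n_perm = 10000L, seed = 1L) {
  stopifnot(is.data.frame(cells), "mean_intensity" %in% names(cells))
  if (nrow(cells) < 3L) stop("need at least 3 cells")
  vars <- setdiff(names(cells)[vapply(cells, is.numeric, logical(1))],
                  c("cell", "mean_intensity"))
  x <- cells$mean_intensity
  res <- lapply(vars, function(v) {
    y <- cells[[v]]
    if (length(unique(y)) < 2L || length(unique(x)) < 2L)
      return(data.frame(variable = v, rho = NA_real_, p_value = NA_real_,
                        n = nrow(cells), note = "constant covariate"))
    rho <- stats::cor(x, y, method = "spearman")
    perm <- local_seed(seed, {
      vapply(seq_len(n_perm), function(i)
        stats::cor(x, sample(y), method = "spearman"), numeric(1))
    })
    p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
    data.frame(variable = v, rho = rho, p_value = p, n = nrow(cells),
               note = "")
  })
  do.call(rbind, res)
}

# evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  expr
}
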