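#' Parameters for prominence-based maxima counting
#'
#' Droplets are counted as local intensity maxima whose topographic
#' prominence -- the minimal intensity drop separating the maximum from any
#' path to a higher maximum -- reaches `prominence`. This is the
#' reproducible counterpart of interactively tuned noise tolerance in
#' point-and-click maxima counting: prominence has an exact definition, so
#' the counter can be verified against a brute-force oracle.
#'
#' @param prominence minimum prominence, in intensity units (> 0).
#' @param abs_threshold intensity floor; maxima with peak value below it are
#'   ignored (>= 0).
#' @param exclude_edges if `TRUE`, maxima whose peak plateau touches the
#'   image border are dropped.
#' @return an object of class `maxima_params`.
#' @export
maxima_params <- function(prominence, abs_threshold = 0,
                          exclude_edges = FALSE) {
  if (!is.numeric(prominence) || prominence <= 0)
    stop("prominence must be > 0")
  if (abs_threshold < 0) stop("abs_threshold must be >= 0")
  structure(list(prominence = prominence,
                 abs_threshold = abs_threshold,
                 exclude_edges = isTRUE(exclude_edges)),
            class = "maxima_params")
}

#' Find local maxima by topographic prominence
#'
#' Detects all local maxima of a 2D frame with prominence at or above
#' `params$prominence` and peak intensity at or above
#' `params$abs_threshold`, under 8-connectivity. Equal-valued plateaus count
#' once and report their centroid. Ties between equal-height peaks are
#' broken deterministically by lexicographic (column-major) pixel order: the
#' peak containing the smaller linear index survives, the other is assigned
#' the saddle-limited prominence. The prominence of the global maximum is
#' its height above the frame minimum.
#'
#' The implementation floods the intensity landscape from above
#' (persistence-style union-find); prominence equals the persistence of the
#' peak's component.
#'
#' @param frame numeric matrix (one movie frame).
#' @param params a [maxima_params] object.
#' @return list with `count` and `maxima`, a data.frame
#'   (`y`, `x` plateau centroid, `value`, `prominence`) ordered by
#'   decreasing value.
#' @export
find_maxima <- function(frame, params) {
  if (!is.matrix(frame)) stop("find_maxima expects a 2D frame (matrix)")
  stopifnot(inherits(params, "maxima_params"))
  ny <- nrow(frame); nx <- ncol(frame)
  n <- ny * nx
  v <- as.vector(frame)
  ord <- order(-v)                       # stable: ties in raster order
  vmin <- v[ord[n]]

  parent <- seq_len(n)
  processed <- logical(n)
  peak_val <- numeric(n); rep_px <- integer(n)
  sum_y <- numeric(n); sum_x <- numeric(n); n_plat <- numeric(n)
  edge <- logical(n)

  res_y <- numeric(0); res_x <- numeric(0)
  res_val <- numeric(0); res_prom <- numeric(0)

  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  emit <- function(r, prom) {
    if (prom >= params$prominence && peak_val[r] >= params$abs_threshold &&
        !(params$exclude_edges && edge[r])) {
      res_y <<- c(res_y, sum_y[r] / n_plat[r])
      res_x <<- c(res_x, sum_x[r] / n_plat[r])
      res_val <<- c(res_val, peak_val[r])
      res_prom <<- c(res_prom, prom)
    }
  }

  # 8-neighbor linear-index table (0 = out of bounds), built once per frame
  idx_grid <- matrix(seq_len(n), ny, nx)
  nb <- matrix(0L, n, 8L)
  k <- 0L
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0L && dy == 0L) next
    k <- k + 1L
    nb[, k] <- as.integer(shift_matrix(idx_grid, dy, dx, 0L))
  }
  border <- rowSums(nb == 0L) > 0L

  for (p in ord) {
    vp <- v[p]
    roots <- integer(0)
    for (q in nb[p, ]) {
      if (q == 0L || !processed[q]) next
      r <- q                             # inline find with path halving
      while (parent[r] != r) {
        parent[r] <- parent[parent[r]]
        r <- parent[r]
      }
      if (!any(roots == r)) roots <- c(roots, r)
    }
    on_border <- border[p]
    y <- ((p - 1L) %% ny) + 1L
    x <- ((p - 1L) %/% ny) + 1L
    if (length(roots) == 0L) {
      peak_val[p] <- vp; rep_px[p] <- p
      sum_y[p] <- y; sum_x[p] <- x; n_plat[p] <- 1
      edge[p] <- on_border
    } else {
      # survivor: highest peak, ties to smallest representative index
      pk <- peak_val[roots]
      best <- which(pk == max(pk))
      if (length(best) > 1L)
        best <- best[which.min(rep_px[roots[best]])]
      s <- roots[best]
      for (d in roots) {
        if (d == s) next
        if (peak_val[d] == vp && peak_val[s] == vp) {
          # two pieces of one plateau meeting at their own level
          sum_y[s] <- sum_y[s] + sum_y[d]
          sum_x[s] <- sum_x[s] + sum_x[d]
          n_plat[s] <- n_plat[s] + n_plat[d]
          edge[s] <- edge[s] || edge[d]
        } else {
          emit(d, peak_val[d] - vp)
        }
        parent[d] <- s
      }
      parent[p] <- s
      if (peak_val[s] == vp) {          # plateau extension
        sum_y[s] <- sum_y[s] + y
        sum_x[s] <- sum_x[s] + x
        n_plat[s] <- n_plat[s] + 1
        edge[s] <- edge[s] || on_border
      }
    }
    processed[p] <- TRUE
  }
  # surviving components: prominence above the global minimum
  roots <- unique(vapply(which(rep_px > 0L), find_root, integer(1)))
  roots <- roots[parent[roots] == roots]
  for (r in roots) emit(r, peak_val[r] - vmin)

  o <- order(-res_val, res_y, res_x)
  list(count = length(o),
       maxima = data.frame(y = res_y[o], x = res_x[o],
                           value = res_val[o], prominence = res_prom[o]))
}

#' @rdname find_maxima
#' @return `find_maxima_count` returns just the integer count.
#' @export
find_maxima_count <- function(frame, params) {
  find_maxima(frame, params)$count
}

# Shared histogram builder for the auto-threshold methods. Integer-valued
# data get one bin per gray level (making thresholds shift-equivariant for
# integer shifts); real-valued data get `n_bins` equal-width bins.
intensity_histogram <- function(x, n_bins = 256L) {
  if (inherits(x, "image_stack")) x <- x$data
  x <- as.vector(x)
  if (length(unique(x)) < 2L)
    stop("constant image: threshold undefined")
  rng <- range(x)
  if (all(x == round(x)) && diff(rng) <= 65535) {
    levels <- seq(rng[1L], rng[2L])
    counts <- tabulate(x - rng[1L] + 1L, nbins = length(levels))
  } else {
    breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    idx <- pmin(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    levels <- breaks[-1L]                 # upper edge of each bin
  }
  list(levels = levels, counts = counts)
}

#' Kapur maximum-entropy threshold
#'
#' Selects the gray level that maximizes the sum of Shannon entropies of the
#' background (at or below the threshold) and foreground (above it) parts of
#' the normalized intensity histogram. Integer images are binned one gray
#' level per bin; real-valued images use `n_bins` equal-width bins and the
#' returned threshold is the upper edge of the selected bin, on the image's
#' own intensity scale. Foreground is everything strictly above the returned
#' value. When several candidate levels tie (e.g. across an empty gap
#' between two populations), the median tied level is returned, which places
#' the threshold centrally between well-separated modes.
#'
#' @param x an [image_stack], matrix/array, or numeric vector.
#' @param n_bins number of bins for real-valued data.
#' @return the threshold, a single number on the intensity scale.
#' @export
max_entropy_threshold <- function(x, n_bins = 256L) {
  h <- intensity_histogram(x, n_bins)
  p <- h$counts / sum(h$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)
  S <- cumsum(plogp)
  Stot <- S[length(S)]
  nb <- length(p)
  t_idx <- seq_len(nb - 1L)
  Pb <- P[t_idx]
  valid <- Pb > 0 & Pb < 1
  Hb <- ifelse(valid, log(Pb) - S[t_idx] / Pb, -Inf)
  Hf <- ifelse(valid, log(1 - Pb) - (Stot - S[t_idx]) / (1 - Pb), -Inf)
  obj <- Hb + Hf
  if (!any(is.finite(obj))) stop("degenerate histogram: threshold undefined")
  tied <- which(obj >= max(obj) - 1e-12)
  h$levels[tied[(length(tied) + 1L) %/% 2L]]
}

#' Triangle threshold
#'
#' Geometric histogram thresholding: a chord is drawn from the histogram
#' peak to the far end of the longer tail (the most distant non-empty bin),
#' and the threshold is the bin whose histogram point lies at maximal
#' perpendicular distance below that chord. Suited to strongly skewed
#' histograms such as a z-stack dominated by background with a small bright
#' droplet population. Ties: the peak bin is the lowest of equally tall
#' bins; among equally distant bins the lowest level is returned; when both
#' tails are equally long the upper tail is used.
#'
#' @inheritParams max_entropy_threshold
#' @return the threshold, a single number on the intensity scale. Foreground
#'   is everything strictly above it.
#' @export
triangle_threshold <- function(x, n_bins = 256L) {
  h <- intensity_histogram(x, n_bins)
  counts <- h$counts
  nz <- which(counts > 0)
  if (length(nz) < 2L) stop("all histogram mass in one bin")
  peak <- which.max(counts)             # lowest of tied peaks
  lo <- nz[1L]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)   # longer tail; tie -> upper side
  tail_bin <- if (right) hi else lo
  if (tail_bin == peak) stop("histogram peak at the extreme bin on both sides")
  idx <- if (right) seq(peak, tail_bin) else seq(tail_bin, peak)
  # perpendicular distance from (i, counts[i]) to the peak--tail chord
  x1 <- peak; y1 <- counts[peak]
  x2 <- tail_bin; y2 <- counts[tail_bin]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1) / len
  best <- idx[which.max(d)]
  h$levels[best]
}

#' Particle analysis of a binary mask
#'
#' Labels connected foreground components (8-connectivity by default, raster
#' label order) and filters them by pixel area, reporting per-particle area,
#' centroid and the equivalent circular diameter.
#'
#' @param mask binary matrix (logical or 0/1).
#' @param min_area_px,max_area_px inclusive area filter in pixels.
#' @param connectivity 4 or 8.
#' @param pixel_size_um optional pixel size; enables `area_um2` and
#'   `equiv_diameter_um`.
#' @return data.frame with one row per retained particle: `label`,
#'   `area_px`, `centroid_y`, `centroid_x`, and if calibrated `area_um2`,
#'   `equiv_diameter_um` (= 2 sqrt(area / pi)).
#' @export
analyze_particles <- function(mask, min_area_px = 1, max_area_px = Inf,
                              connectivity = 8L, pixel_size_um = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(as.vector(mask) %in% c(0, 1, TRUE, FALSE)))
    stop("analyze_particles requires a binary mask")
  labels <- label_components(mask, connectivity)
  nlab <- max(labels)
  if (nlab == 0L) {
    out <- data.frame(label = integer(0), area_px = integer(0),
                      centroid_y = numeric(0), centroid_x = numeric(0))
  } else {
    areas <- tabulate(labels[labels > 0L], nbins = nlab)
    idx <- which(labels > 0L)
    co <- arrayInd(idx, dim(mask))
    lab <- labels[idx]
    cy <- rowsum(as.numeric(co[, 1L]), lab)[, 1L] / areas
    cx <- rowsum(as.numeric(co[, 2L]), lab)[, 1L] / areas
    out <- data.frame(label = seq_len(nlab), area_px = areas,
                      centroid_y = cy, centroid_x = cx)
    out <- out[out$area_px >= min_area_px & out$area_px <= max_area_px, ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  if (!is.null(pixel_size_um) && nrow(out) >= 0L) {
    out$area_um2 <- out$area_px * pixel_size_um^2
    out$equiv_diameter_um <- 2 * sqrt(out$area_um2 / pi)
  }
  out
}

#' One-pixel binary outline
#'
#' The boundary of a binary mask: the mask minus its erosion by the 3x3
#' square element (pixels outside the image count as background, so objects
#' touching the border contribute their border pixels).
#'
#' @param mask binary matrix.
#' @return logical matrix marking the 1-pixel-wide outline.
#' @export
binary_outline <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  m <- mask != 0
  er <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    er <- er & shift_matrix(m, dy, dx, FALSE)
  }
  m & !er
}

#' Ca2+ gate from a fluorescence trace
#'
#' Boolean per-frame gate marking frames with elevated cytosolic Ca2+:
#' `TRUE` where the intensity trace exceeds `gate_factor` times its mean
#' over the pre-stimulus baseline frames.
#'
#' @param intensity numeric per-frame intensity trace.
#' @param baseline_frames indices of pre-stimulus frames.
#' @param gate_factor multiple of the baseline mean that defines "elevated".
#' @return logical vector, one element per frame.
#' @export
ca_gate_from_trace <- function(intensity, baseline_frames,
                               gate_factor = 1.5) {
  base <- mean(intensity[baseline_frames])
  if (!is.finite(base) || base <= 0)
    stop("baseline intensity must be positive to derive a Ca gate")
  intensity > gate_factor * base
}

#' Dual-threshold droplet counting for single-channel dual reporters
#'
#' With a dual Ca2+/kinase reporter read through one channel, elevated Ca2+
#' raises all reporter fluorescence, so a single intensity floor cannot
#' serve both Ca2+ states. Two concurrent counts are therefore produced:
#' one with a high intensity floor (valid while Ca2+ is elevated) and one
#' with a low floor (valid at resting Ca2+). The merged trace takes, on
#' each frame, the count from the threshold matching the frame's Ca2+
#' state, as given by `ca_gate`; both raw traces are returned alongside so
#' the merge can always be audited or redone by hand.
#'
#' @param movie a `TYX` [image_stack] (already background subtracted).
#' @param cell_mask logical matrix selecting the cell; only maxima inside
#'   it are counted.
#' @param low_thr,high_thr intensity floors, `low_thr < high_thr`.
#' @param prominence minimum prominence for maxima counting.
#' @param ca_gate logical per-frame vector (`TRUE` = elevated Ca2+), e.g.
#'   from [ca_gate_from_trace].
#' @param exclude_edges passed to [maxima_params].
#' @return data.frame with one row per frame: `frame`, `time_s`,
#'   `count_low`, `count_high`, `ca_gate`, `count_merged`.
#' @export
dual_threshold_count <- function(movie, cell_mask, low_thr, high_thr,
                                 prominence, ca_gate,
                                 exclude_edges = FALSE) {
  stopifnot(inherits(movie, "image_stack"), movie$axes == "TYX")
  if (!(low_thr < high_thr)) stop("low_thr must be below high_thr")
  nf <- n_frames(movie)
  if (length(ca_gate) != nf)
    stop("ca_gate length (", length(ca_gate),
         ") does not match the number of frames (", nf, ")")
  if (!all(dim(cell_mask) == dim(movie$data)[2:3]))
    stop("cell mask dimensions do not match the movie frames")
  p_low <- maxima_params(prominence, low_thr, exclude_edges)
  p_high <- maxima_params(prominence, high_thr, exclude_edges)
  count_in_mask <- function(frame, params) {
    mx <- find_maxima(frame, params)$maxima
    if (nrow(mx) == 0L) return(0L)
    yy <- pmin(pmax(round(mx$y), 1L), nrow(cell_mask))
    xx <- pmin(pmax(round(mx$x), 1L), ncol(cell_mask))
    sum(cell_mask[cbind(yy, xx)])
  }
  cl <- ch <- integer(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(movie, i)
    cl[i] <- count_in_mask(fr, p_low)
    ch[i] <- count_in_mask(fr, p_high)
  }
  data.frame(frame = seq_len(nf),
             time_s = (seq_len(nf) - 1L) * movie$frame_interval_s,
             count_low = cl, count_high = ch,
             ca_gate = as.logical(ca_gate),
             count_merged = ifelse(ca_gate, ch, cl))
}
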