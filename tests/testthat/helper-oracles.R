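# Independent brute-force oracles used to verify the detection and
# thresholding algorithms. These are deliberately naive (flood searches,
# exhaustive scans) and share no code with the implementations they check.

# --- 8-neighbor helper on a matrix -----------------------------------------
oracle_neighbors <- function(i, ny, nx) {
  y <- ((i - 1L) %% ny) + 1L
  x <- ((i - 1L) %/% ny) + 1L
  out <- integer(0)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    yy <- y + dy; xx <- x + dx
    if (yy >= 1L && yy <= ny && xx >= 1L && xx <= nx)
      out <- c(out, (xx - 1L) * ny + yy)
  }
  out
}

# flood the connected component of {v >= level} containing `seed` pixels
oracle_flood <- function(v, ny, nx, seeds, level) {
  inset <- v >= level
  visited <- logical(length(v))
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (p in frontier) {
      for (q in oracle_neighbors(p, ny, nx)) {
        if (inset[q] && !visited[q]) {
          visited[q] <- TRUE
          nxt <- c(nxt, q)
        }
      }
    }
    frontier <- nxt
  }
  which(visited)
}

# Brute-force prominence-based maxima count. Plateaus (equal-value connected
# sets) count once; ties between equal-height peaks are broken by the
# smallest linear pixel index, mirroring the documented convention.
oracle_count_maxima <- function(frame, prominence, abs_threshold = 0) {
  ny <- nrow(frame); nx <- ncol(frame)
  v <- as.vector(frame)
  n <- length(v)
  vmin <- min(v)
  # plateau labelling
  plat <- integer(n)
  np <- 0L
  for (s in seq_len(n)) {
    if (plat[s] != 0L) next
    np <- np + 1L
    plat[s] <- np
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (p in frontier) for (q in oracle_neighbors(p, ny, nx)) {
        if (plat[q] == 0L && v[q] == v[p]) {
          plat[q] <- np
          nxt <- c(nxt, q)
        }
      }
      frontier <- nxt
    }
  }
  plat_min_idx <- vapply(seq_len(np), function(k) min(which(plat == k)),
                         integer(1))
  count <- 0L
  for (k in seq_len(np)) {
    members <- which(plat == k)
    v0 <- v[members[1L]]
    if (v0 < abs_threshold) next
    # local maximum: no strictly higher neighbor
    higher <- FALSE
    for (p in members) for (q in oracle_neighbors(p, ny, nx))
      if (v[q] > v0) higher <- TRUE
    if (higher) next
    # prominence: highest flood level reaching a "higher" peak, where a
    # same-height plateau with a smaller min index also counts as higher
    levels <- sort(unique(v[v <= v0]), decreasing = TRUE)
    prom <- v0 - vmin
    for (L in levels) {
      comp <- oracle_flood(v, ny, nx, members, L)
      beats <- any(v[comp] > v0) ||
        any(v[comp] == v0 & plat[comp] != k &
              plat_min_idx[plat[comp]] < plat_min_idx[k])
      if (beats) {
        prom <- v0 - L
        break
      }
    }
    if (prom >= prominence) count <- count + 1L
  }
  count
}

# --- exhaustive Kapur objective scan ---------------------------------------
oracle_max_entropy <- function(levels, counts) {
  p <- counts / sum(counts)
  nb <- length(p)
  best <- -Inf; best_t <- integer(0)
  for (t in seq_len(nb - 1L)) {
    Pb <- sum(p[1:t])
    if (Pb <= 0 || Pb >= 1) next
    pb <- p[1:t] / Pb
    pf <- p[(t + 1L):nb] / (1 - Pb)
    Hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
    Hf <- -sum(ifelse(pf > 0, pf * log(pf), 0))
    obj <- Hb + Hf
    if (obj > best + 1e-12) {
      best <- obj; best_t <- t
    } else if (obj >= best - 1e-12) {
      best_t <- c(best_t, t)
    }
  }
  levels[best_t[(length(best_t) + 1L) %/% 2L]]
}

# --- exhaustive Triangle geometric scan ------------------------------------
oracle_triangle <- function(levels, counts) {
  nz <- which(counts > 0)
  peak <- which(counts == max(counts))[1L]
  lo <- nz[1L]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)
  tail_bin <- if (right) hi else lo
  idx <- if (right) peak:tail_bin else tail_bin:peak
  p1 <- c(peak, counts[peak]); p2 <- c(tail_bin, counts[tail_bin])
  dmax <- -Inf; best <- idx[1L]
  for (i in idx) {
    # distance from point (i, counts[i]) to the line p1-p2
    num <- abs((p2[2] - p1[2]) * i - (p2[1] - p1[1]) * counts[i] +
                 p2[1] * p1[2] - p2[2] * p1[1])
    d <- num / sqrt(sum((p2 - p1)^2))
    if (d > dmax) {
      dmax <- d; best <- i
    }
  }
  levels[best]
}

# --- recursive flood-fill component count ----------------------------------
oracle_component_count <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  fg <- as.vector(mask != 0)
  seen <- logical(length(fg))
  conn4 <- connectivity == 4L
  count <- 0L
  for (s in which(fg)) {
    if (seen[s]) next
    count <- count + 1L
    seen[s] <- TRUE
    stack <- s
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (q in oracle_neighbors(p, ny, nx)) {
        if (conn4) {
          dy <- abs(((q - 1L) %% ny) - ((p - 1L) %% ny))
          dx <- abs(((q - 1L) %/% ny) - ((p - 1L) %/% ny))
          if (dy + dx != 1L) next
        }
        if (fg[q] && !seen[q]) {
          seen[q] <- TRUE
          stack <- c(stack, q)
        }
      }
    }
  }
  count
}

# random integer histogram over integer gray levels starting at `lo`
random_histogram <- function(n_bins = 64L, lo = 0L) {
  counts <- rpois(n_bins, lambda = sample(c(0.5, 3, 20), n_bins,
                                          replace = TRUE))
  if (sum(counts > 0) < 2L) counts[c(1L, n_bins)] <- counts[c(1L, n_bins)] + 1L
  list(levels = seq(lo, lo + n_bins - 1L), counts = counts)
}

# expand a histogram into raw data (the package thresholds take data)
histogram_data <- function(h) rep(h$levels, h$counts)

# --- naive non-flat ball opening (rolling-ball background oracle) ----------
# direct double-loop erosion/dilation; shares no code with the implementation
oracle_rolling_background <- function(img, radius) {
  ny <- nrow(img); nx <- ncol(img)
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  er <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    best <- Inf
    for (k in seq_len(nrow(offs))) {
      yy <- y + offs$dy[k]; xx <- x + offs$dx[k]
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      best <- min(best, img[yy, xx] - offs$h[k])
    }
    er[y, x] <- best
  }
  di <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    best <- -Inf
    for (k in seq_len(nrow(offs))) {
      yy <- y - offs$dy[k]; xx <- x - offs$dx[k]
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      best <- max(best, er[yy, xx] + offs$h[k])
    }
    di[y, x] <- best
  }
  di
}
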