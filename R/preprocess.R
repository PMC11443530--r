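#' Background subtraction with a background ROI
#'
#' For every frame, the mean intensity inside a signal-free background region
#' is subtracted from the whole frame and the result is clamped at zero.
#' This removes the camera offset plus any spatially flat ambient component
#' and is the first step of the quantitative trace pipeline.
#'
#' @param stack an [image_stack].
#' @param roi a background [roi_mask] (`label = "background"`).
#' @return a real-valued `image_stack` of the same shape.
#' @export
subtract_background_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi"))
  if (roi$label != "background")
    stop("subtract_background_roi needs an ROI with label 'background'")
  if (!any(roi$mask)) stop("ROI overlaps no pixels")
  fd <- if (stack$axes == "YX") dim(stack$data) else dim(stack$data)[2:3]
  if (!all(dim(roi$mask) == fd))
    stop("ROI dimensions do not match the image frame")
  stack_map(stack, function(fr, i) {
    pmax(fr - mean(fr[roi$mask]), 0)
  })
}

# Non-flat ball structuring element: offsets within `radius` and the
# ball-cap height at each offset.
ball_element <- function(radius) {
  r <- floor(radius)
  d <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- d$dy^2 + d$dx^2 <= radius^2
  d <- d[keep, , drop = FALSE]
  list(dy = d$dy, dx = d$dx,
       h = sqrt(pmax(radius^2 - d$dy^2 - d$dx^2, 0)))
}

# shift a matrix by (dy, dx), filling vacated cells with `fill`
shift_matrix <- function(m, dy, dx, fill) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1L, 1L + dy):min(ny, ny + dy)
  xs <- max(1L, 1L + dx):min(nx, nx + dx)
  if (length(ys) > 0L && length(xs) > 0L)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

# grayscale erosion / dilation by a non-flat ball element
gray_erode_ball <- function(m, se) {
  acc <- matrix(Inf, nrow(m), ncol(m))
  for (k in seq_along(se$h)) {
    acc <- pmin(acc, shift_matrix(m, -se$dy[k], -se$dx[k], Inf) - se$h[k])
  }
  acc
}
gray_dilate_ball <- function(m, se) {
  acc <- matrix(-Inf, nrow(m), ncol(m))
  for (k in seq_along(se$h)) {
    acc <- pmax(acc, shift_matrix(m, se$dy[k], se$dx[k], -Inf) + se$h[k])
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' The background of each frame is estimated as the grayscale opening of the
#' frame by a ball-shaped (non-flat) structuring element of the given radius
#' -- the envelope traced by rolling a ball of that radius under the
#' intensity landscape -- and subtracted. Features narrower than the ball
#' (droplets) cannot accommodate it and are preserved; smooth background
#' variation wider than the ball is removed. The result is clamped at zero.
#'
#' A practical radius is several times the expected droplet radius in
#' pixels, so that no droplet is flattened into the background estimate.
#'
#' @param stack an [image_stack].
#' @param radius_px ball radius in pixels (>= 1).
#' @return a real-valued `image_stack`, same shape, all values >= 0.
#' @export
rolling_ball_subtract <- function(stack, radius_px) {
  stopifnot(inherits(stack, "image_stack"))
  if (radius_px < 1) stop("radius_px must be >= 1")
  fd <- if (stack$axes == "YX") dim(stack$data) else dim(stack$data)[2:3]
  if (radius_px > max(fd)) stop("ball radius exceeds the image size")
  se <- ball_element(radius_px)
  stack_map(stack, function(fr, i) {
    bg <- gray_dilate_ball(gray_erode_ball(fr, se), se)
    pmax(fr - bg, 0)
  })
}

#' Pixel-wise self-multiplication
#'
#' Squares every pixel. A strictly monotone transform on non-negative data,
#' so it preserves intensity ordering while stretching relative contrast:
#' for any peak > background > 0 the ratio (peak - bg) / bg strictly grows.
#' Used to sharpen droplets against residual diffuse signal before
#' histogram thresholding.
#'
#' @param stack an [image_stack].
#' @return a real-valued `image_stack` with squared intensities.
#' @export
self_multiply <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  out <- stack
  out$data <- stack$data^2
  out
}

#' Linear rescale to 8-bit
#'
#' Maps `[lo, hi]` linearly onto `[0, 255]`, clips outside the range, and
#' rounds half-up to integers. Defaults use the global minimum and maximum
#' of the stack, so one consistent mapping (and one histogram) covers a
#' whole z-stack.
#'
#' @param stack an [image_stack].
#' @param lo,hi input range; defaults to the stack min / max.
#' @return an `image_stack` with integer values in 0..255.
#' @export
rescale_to_8bit <- function(stack, lo = NULL, hi = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(lo)) lo <- min(stack$data)
  if (is.null(hi)) hi <- max(stack$data)
  if (!(hi > lo))
    stop("degenerate intensity range: hi must exceed lo ",
         "(constant image with default range?)")
  out <- stack
  v <- 255 * (stack$data - lo) / (hi - lo)
  out$data <- array(pmin(pmax(floor(v + 0.5), 0), 255), dim(stack$data))
  out
}

#' Per-frame display normalization
#'
#' Rescales each frame linearly with the frame mean as the display floor and
#' the frame maximum as the ceiling, clipped to `[0, 1]`. This reproduces
#' setting the displayed minimum and maximum to each frame's mean and
#' maximal fluorescence; it is a display/segmentation aid and must never be
#' used for quantitative intensity traces.
#'
#' @param stack an [image_stack] movie.
#' @return an `image_stack` with values in `[0, 1]`.
#' @export
display_normalize_per_frame <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  stack_map(stack, function(fr, i) {
    lo <- mean(fr); hi <- max(fr)
    if (hi <= lo) {
      warning("frame ", i, " is constant; normalized to 0")
      return(matrix(0, nrow(fr), ncol(fr)))
    }
    pmin(pmax((fr - lo) / (hi - lo), 0), 1)
  })
}
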