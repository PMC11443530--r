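#' Calibrated image stack
#'
#' The central container of the package: a 2D frame, a T-series movie or a
#' confocal z-stack, together with its physical calibration. Data are stored
#' as a numeric matrix (single frame, `Y x X`) or a 3D array with the leading
#' axis being time or depth (`T x Y x X` or `Z x Y x X`).
#'
#' @param data numeric matrix (`axes = "YX"`) or 3D array (`"TYX"` / `"ZYX"`).
#' @param axes one of `"YX"`, `"TYX"`, `"ZYX"`.
#' @param pixel_size_um lateral pixel size in micrometres per pixel (> 0).
#' @param z_step_um axial spacing in micrometres per slice; required for
#'   `"ZYX"` stacks.
#' @param frame_interval_s acquisition interval in seconds; required for
#'   `"TYX"` movies.
#'
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, axes = c("YX", "TYX", "ZYX"),
                        pixel_size_um, z_step_um = NULL,
                        frame_interval_s = NULL) {
  axes <- match.arg(axes)
  if (axes == "YX") {
    if (!is.matrix(data)) stop("'YX' data must be a matrix")
  } else {
    if (!(is.array(data) && length(dim(data)) == 3L))
      stop("'", axes, "' data must be a 3D array")
  }
  if (!is.numeric(data) || anyNA(data))
    stop("image data must be numeric and free of NA")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (axes == "ZYX") {
    if (is.null(z_step_um) || z_step_um <= 0)
      stop("z-stacks require a positive z_step_um")
  }
  if (axes == "TYX") {
    if (is.null(frame_interval_s) || frame_interval_s <= 0)
      stop("movies require a positive frame_interval_s")
  }
  structure(
    list(data = data, axes = axes,
         pixel_size_um = as.numeric(pixel_size_um),
         z_step_um = if (is.null(z_step_um)) NULL else as.numeric(z_step_um),
         frame_interval_s = if (is.null(frame_interval_s)) NULL
                            else as.numeric(frame_interval_s)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  if (is.null(d)) d <- c(length(x$data))
  cat("<image_stack> axes:", x$axes, " dim:", paste(d, collapse = " x "),
      "\n  pixel size:", x$pixel_size_um, "um/px")
  if (!is.null(x$z_step_um)) cat("  z step:", x$z_step_um, "um")
  if (!is.null(x$frame_interval_s))
    cat("  frame interval:", x$frame_interval_s, "s")
  cat("\n  intensity range: [", format(min(x$data)), ",",
      format(max(x$data)), "]\n")
  invisible(x)
}

#' Number of frames (or z-slices) in a stack
#' @param stack an `image_stack`.
#' @return integer count; 1 for a single frame.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axes == "YX") 1L else dim(stack$data)[1L]
}

#' Extract one frame as a matrix
#' @param stack an `image_stack`.
#' @param i frame (or slice) index, 1-based.
#' @return numeric `Y x X` matrix.
#' @export
get_frame <- function(stack, i) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axes == "YX") {
    if (i != 1L) stop("single-frame stack has no frame ", i)
    return(stack$data)
  }
  d <- dim(stack$data)
  if (i < 1L || i > d[1L]) stop("frame index out of range")
  matrix(stack$data[i, , ], d[2L], d[3L])
}

# Apply `fun(frame_matrix, frame_index)` to every frame, preserving shape
# and calibration. Used by all per-frame-independent preprocessing ops.
stack_map <- function(stack, fun) {
  if (stack$axes == "YX") {
    out <- stack
    out$data <- fun(stack$data, 1L)
    return(out)
  }
  d <- dim(stack$data)
  res <- array(0, d)
  for (i in seq_len(d[1L])) res[i, , ] <- fun(get_frame(stack, i), i)
  out <- stack
  out$data <- res
  out
}

# internal: coerce a bare matrix/array into image_stack for convenience
as_stack <- function(x, template) {
  out <- template
  out$data <- x
  out
}
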