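#' Region of interest
#'
#' An ROI is a labelled pixel mask over the image plane, used to mark a cell
#' footprint or a signal-free background region. ROIs can be built from a
#' logical mask, a rectangle, an ellipse, or a polygon (even-odd rule).
#'
#' @param mask logical matrix (`Y x X`), `TRUE` inside the region.
#' @param label `"cell"` or `"background"`.
#' @return an object of class `roi`.
#' @export
roi_mask <- function(mask, label = c("cell", "background")) {
  label <- match.arg(label)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask != 0
  if (!any(mask)) stop("ROI overlaps no pixels")
  structure(list(mask = mask, label = label), class = "roi")
}

#' @rdname roi_mask
#' @param y,x 1-based pixel ranges of the rectangle.
#' @param dim image dimensions `c(ny, nx)`.
#' @export
roi_rect <- function(y, x, dim, label = c("cell", "background")) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  m[y, x] <- TRUE
  roi_mask(m, match.arg(label))
}

#' @rdname roi_mask
#' @param center_px ellipse centre `c(y, x)` in pixels.
#' @param radii_px semi-axes `c(ry, rx)` in pixels.
#' @export
roi_ellipse <- function(center_px, radii_px, dim,
                        label = c("cell", "background")) {
  yy <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  xx <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  m <- ((yy - center_px[1L]) / radii_px[1L])^2 +
       ((xx - center_px[2L]) / radii_px[2L])^2 <= 1
  roi_mask(m, match.arg(label))
}

#' @rdname roi_mask
#' @param vertices two-column matrix of polygon vertices `(y, x)` in pixel
#'   coordinates; the polygon is closed implicitly.
#' @export
roi_polygon <- function(vertices, dim, label = c("cell", "background")) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2L, nrow(vertices) >= 3L)
  ny <- dim[1L]; nx <- dim[2L]
  py <- vertices[, 1L]; px <- vertices[, 2L]
  yy <- rep(seq_len(ny), nx)
  xx <- rep(seq_len(nx), each = ny)
  inside <- rep(FALSE, ny * nx)
  n <- nrow(vertices)
  j <- n
  for (i in seq_len(n)) {           # even-odd ray casting
    crosses <- ((py[i] > yy) != (py[j] > yy)) &
      (xx < (px[j] - px[i]) * (yy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  roi_mask(matrix(inside, ny, nx), match.arg(label))
}

#' Read / write ROIs as JSON
#'
#' ROIs are serialized as a list of objects with a `label` and either a
#' `polygon` (vertex list) or dense `mask` run-length encoding.
#'
#' @param rois list of `roi` objects.
#' @param path JSON file path.
#' @param dim image dimensions `c(ny, nx)` used to rasterize polygons.
#' @return `read_rois` returns a list of `roi` objects.
#' @export
write_rois <- function(rois, path) {
  enc <- lapply(rois, function(r) {
    idx <- which(r$mask) - 1L                       # 0-based linear indices
    list(label = r$label, dim = dim(r$mask), which = idx)
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path, dim = NULL) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(enc)) enc <- split(enc, seq_len(nrow(enc)))
  lapply(enc, function(e) {
    if (!is.null(e$polygon)) {
      roi_polygon(matrix(unlist(e$polygon), ncol = 2L, byrow = TRUE),
                  dim = dim %||% unlist(e$dim), label = e$label)
    } else {
      d <- unlist(e$dim)
      m <- matrix(FALSE, d[1L], d[2L])
      m[unlist(e$which) + 1L] <- TRUE
      roi_mask(m, e$label)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
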