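# Connected-component labelling shared by 2D particle analysis and 3D
# condensate segmentation. One breadth-first engine serves both: labels are
# assigned in array linear-index (raster) order, so labelling is fully
# deterministic for a given mask and connectivity.

neighbor_offsets <- function(ndim, connectivity) {
  if (ndim == 2L) {
    if (!connectivity %in% c(4L, 8L))
      stop("2D connectivity must be 4 or 8")
    d <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    d <- d[rowSums(abs(d)) > 0L, , drop = FALSE]
    if (connectivity == 4L) d <- d[rowSums(abs(d)) == 1L, , drop = FALSE]
    return(d)
  }
  if (ndim == 3L) {
    if (!connectivity %in% c(6L, 18L, 26L))
      stop("3D connectivity must be 6, 18 or 26")
    d <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    d <- d[rowSums(abs(d)) > 0L, , drop = FALSE]
    keep <- switch(as.character(connectivity),
                   "6"  = rowSums(abs(d)) == 1L,
                   "18" = rowSums(abs(d)) <= 2L,
                   "26" = rep(TRUE, nrow(d)))
    return(d[keep, , drop = FALSE])
  }
  stop("only 2D and 3D masks are supported")
}

#' Label connected components of a binary mask
#'
#' @param mask logical/0-1 matrix (2D) or 3D array.
#' @param connectivity 4 or 8 in 2D (default 8); 6, 18 or 26 in 3D
#'   (default 26).
#' @return integer array of the same shape; 0 = background, components are
#'   numbered 1, 2, ... in raster (array linear index) order of their first
#'   voxel.
#' @export
label_components <- function(mask, connectivity = NULL) {
  dm <- dim(mask)
  ndim <- length(dm)
  if (is.null(connectivity)) connectivity <- if (ndim == 2L) 8L else 26L
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask must be binary (0/1 or logical)")
  fg <- as.vector(mask) != 0
  labels <- integer(length(fg))
  offs <- neighbor_offsets(ndim, as.integer(connectivity))
  # strides for linear indexing
  strides <- cumprod(c(1L, dm[-ndim]))
  off_lin <- as.integer(offs %*% strides)
  next_label <- 0L
  seeds <- which(fg)
  for (s in seeds) {
    if (labels[s] != 0L) next
    next_label <- next_label + 1L
    labels[s] <- next_label
    frontier <- s
    while (length(frontier) > 0L) {
      # coordinates of the frontier, 1-based
      co <- arrayInd(frontier, dm)
      cand_lin <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nc <- co + matrix(offs[k, ], nrow(co), ndim, byrow = TRUE)
        ok <- rep(TRUE, nrow(nc))
        for (a in seq_len(ndim))
          ok <- ok & nc[, a] >= 1L & nc[, a] <= dm[a]
        if (!any(ok)) next
        lin <- frontier[ok] + off_lin[k]
        cand_lin <- c(cand_lin, lin)
      }
      cand_lin <- unique(cand_lin)
      cand_lin <- cand_lin[fg[cand_lin] & labels[cand_lin] == 0L]
      labels[cand_lin] <- next_label
      frontier <- cand_lin
    }
  }
  array(labels, dm)
}
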