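#' Integrated fluorescence intensity trace of a cell
#'
#' Per-frame background-subtracted fluorescence integrated (summed, not
#' averaged) over the cell mask. For a dual Ca2+/kinase reporter the
#' integrated trace reports cytosolic Ca2+: condensation only redistributes
#' reporter molecules within the cell, so the integral tracks the
#' per-molecule brightness set by Ca2+ while being insensitive to droplet
#' formation.
#'
#' @param movie a `TYX` [image_stack].
#' @param cell_mask logical matrix selecting the cell.
#' @param background_roi optional background [roi_mask]; its per-frame mean
#'   is subtracted before integration.
#' @param stat `"sum"` (integrated, the default) or `"mean"`.
#' @return numeric vector, one value per frame.
#' @export
gcamp_intensity_trace <- function(movie, cell_mask, background_roi = NULL,
                                  stat = c("sum", "mean")) {
  stopifnot(inherits(movie, "image_stack"), movie$axes == "TYX")
  stat <- match.arg(stat)
  if (!all(dim(cell_mask) == dim(movie$data)[2:3]))
    stop("cell mask dimensions do not match the movie frames")
  if (!any(cell_mask)) stop("empty cell mask")
  nf <- n_frames(movie)
  out <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(movie, i)
    if (!is.null(background_roi)) fr <- fr - mean(fr[background_roi$mask])
    out[i] <- if (stat == "sum") sum(fr[cell_mask]) else mean(fr[cell_mask])
  }
  out
}

#' Droplet formation latency
#'
#' Time from stimulus onset to the first sustained droplet response: the
#' first frame at or after `onset_frame` where the cluster count is at
#' least `k_min_clusters` for `m_sustained_frames` consecutive frames.
#' Returned in minutes. Cells that never meet the criterion are
#' non-responders and return `NA` (reported as "no response"), as seen in
#' injury paradigms where only a subset of cells responds.
#'
#' @param count integer per-frame cluster-count trace.
#' @param onset_frame 1-based frame index of stimulus onset.
#' @param frame_interval_s seconds per frame.
#' @param k_min_clusters response threshold on the count (default 3).
#' @param m_sustained_frames consecutive frames required (default 2).
#' @return latency in minutes, or `NA_real_` for non-responders.
#' @export
formation_latency <- function(count, onset_frame, frame_interval_s,
                              k_min_clusters = 3L, m_sustained_frames = 2L) {
  nf <- length(count)
  if (onset_frame < 1L || onset_frame > nf)
    stop("onset_frame is outside the trace")
  stopifnot(k_min_clusters >= 1L, m_sustained_frames >= 1L)
  ok <- count >= k_min_clusters
  for (f in onset_frame:nf) {
    if (f + m_sustained_frames - 1L > nf) break
    if (all(ok[f:(f + m_sustained_frames - 1L)]))
      return((f - onset_frame) * frame_interval_s / 60)
  }
  NA_real_
}

#' Washout dispersion fraction
#'
#' Percentage of peak-window clusters that have dissolved by the washout
#' window: `100 * (max count in peak window - min count in washout window)
#' / max count in peak window`. The washout minimum (rather than the
#' endpoint) makes the estimate robust to re-nucleation blips. A cell with
#' zero peak count has an undefined fraction and returns `NA`.
#'
#' @param count integer per-frame cluster-count trace.
#' @param peak_window,washout_window frame index vectors; must be disjoint,
#'   with the washout after the peak window.
#' @return dispersion percentage (100 = complete dispersal; negative values
#'   indicate net growth after washout), or `NA` if the peak count is 0.
#' @export
dispersion_fraction <- function(count, peak_window, washout_window) {
  if (length(intersect(peak_window, washout_window)) > 0L)
    stop("peak and washout windows must be disjoint")
  if (min(washout_window) <= max(peak_window))
    stop("washout window must come after the peak window")
  pk <- max(count[peak_window])
  if (pk == 0) return(NA_real_)
  100 * (pk - min(count[washout_window])) / pk
}

#' Population dispersion summary
#'
#' Mean and standard deviation of [dispersion_fraction] across cells.
#'
#' @param counts list of per-cell count traces.
#' @inheritParams dispersion_fraction
#' @return list with `per_cell`, `mean`, `sd`, `n` (cells with a defined
#'   fraction).
#' @export
dispersion_summary <- function(counts, peak_window, washout_window) {
  per <- vapply(counts, dispersion_fraction, numeric(1),
                peak_window = peak_window, washout_window = washout_window)
  ok <- !is.na(per)
  list(per_cell = per, mean = mean(per[ok]),
       sd = stats::sd(per[ok]), n = sum(ok))
}

#' Normalize traces to each cell's own maximum
#'
#' For single-cell heatmaps, each cell's cluster count and intensity are
#' divided by that cell's own maximum, mapping every trace into `[0, 1]`
#' so cells of different expression levels share one color scale. Cells
#' whose trace is all zero are left unnormalized with a warning.
#'
#' @param traces long-format data.frame with columns `cell`, `frame`, and
#'   any of `count`, `intensity`.
#' @return the input with added `count_norm` / `intensity_norm` columns.
#' @export
normalize_for_heatmap <- function(traces) {
  stopifnot(is.data.frame(traces), all(c("cell", "frame") %in% names(traces)))
  for (v in intersect(c("count", "intensity"), names(traces))) {
    nv <- paste0(v, "_norm")
    traces[[nv]] <- NA_real_
    for (cl in unique(traces$cell)) {
      sel <- traces$cell == cl
      mx <- max(traces[[v]][sel])
      if (mx <= 0) {
        warning("cell ", cl, ": all-zero ", v, " trace left unnormalized")
        traces[[nv]][sel] <- traces[[v]][sel]
      } else {
        traces[[nv]][sel] <- traces[[v]][sel] / mx
      }
    }
  }
  traces
}
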